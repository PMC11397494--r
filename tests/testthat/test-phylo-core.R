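test_that("Newick parsing validates and round-trips", {
  tr <- readSpeciesTree("((A:0.1,B:0.1):0.2,C:0.3);")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(sort(tr$edge.length), c(0.1, 0.1, 0.2, 0.3))

  tr1 <- readSpeciesTree("(A:0.5);")
  expect_equal(tr1$tip.label, "A")

  expect_error(readSpeciesTree("((A:0.1,A:0.2):0.1,B:0.3);"),
               "duplicate leaf label")
  expect_error(readSpeciesTree("((A:0.1,B:"), "malformed")

  # write-then-parse preserves topology and lengths on random 11-leaf trees
  for (s in 1:5) {
    tr <- randomTree(11, seed = s)
    tr2 <- readSpeciesTree(writeSpeciesTree(tr))
    expect_equal(as.numeric(suppressWarnings(ape::dist.topo(tr, tr2))), 0)
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-10)
  }
})

test_that("HKY transition matrices satisfy their invariants", {
  m <- hky85(c(0.3, 0.2, 0.2, 0.3), kappa = 2.5)
  expect_error(transitionMatrix(m, -0.1), "non-negative")

  expect_equal(transitionMatrix(m, 0), diag(4), ignore_attr = TRUE)
  Pbig <- transitionMatrix(m, 100)
  for (i in 1:4) expect_equal(unname(Pbig[i, ]), unname(m@freqs),
                              tolerance = 1e-8)
  for (t in c(0.05, 0.3, 1.2)) {
    P <- transitionMatrix(m, t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    # detailed balance pi_i P_ij = pi_j P_ji
    expect_lt(max(abs(m@freqs * P - t(m@freqs * P))), 1e-12)
  }

  # Jukes-Cantor closed form at equal frequencies, kappa = 1
  jc <- hky85()
  P <- transitionMatrix(jc, 0.3)
  expect_equal(P[1, 1], 1 / 4 + 3 / 4 * exp(-4 * 0.3 / 3),
               tolerance = 1e-12)
  expect_equal(P[1, 2], 1 / 4 - 1 / 4 * exp(-4 * 0.3 / 3),
               tolerance = 1e-12)

  # model validity errors
  expect_error(hky85(c(0.5, 0.5, 0.2, 0.2)), "sum to 1")
  expect_error(hky85(kappa = -1), "kappa")
})

test_that("column log-likelihood matches closed forms and enumeration", {
  jc <- hky85()
  tr1 <- readSpeciesTree("(A:0.5);")
  expect_equal(columnLoglik(tr1, jc, c(A = "A")), log(0.25))

  tr2 <- readSpeciesTree("(A:0.2,B:0.3);")
  expect_equal(columnLoglik(tr2, jc, c(A = "A", B = "A")),
               log(0.25 * (1 / 4 + 3 / 4 * exp(-4 * 0.5 / 3))),
               tolerance = 1e-12)

  m <- hky85(c(0.3, 0.2, 0.2, 0.3), kappa = 2)
  tr4 <- readSpeciesTree("((A:0.1,B:0.25):0.15,(C:0.3,D:0.05):0.2);")
  for (col in list(c(A = "A", B = "C", C = "G", D = "A"),
                   c(A = "T", B = "T", C = "T", D = "T"),
                   c(A = "A", B = "N", C = "G", D = "-"))) {
    expect_equal(columnLoglik(tr4, m, col),
                 bruteColumnLoglik(tr4, m, col), tolerance = 1e-10)
  }
  expect_error(columnLoglik(tr4, m, c(A = "X", B = "A", C = "A", D = "A")),
               "unknown alignment symbol")
  expect_error(columnLoglik(tr4, m, c(A = "A", B = "A", C = "A")),
               "lacks a symbol")
})

test_that("alignment log-likelihood is additive and handles missing data", {
  m <- hky85(c(0.3, 0.2, 0.2, 0.3), kappa = 2)
  tr <- readSpeciesTree("((A:0.1,B:0.25):0.15,(C:0.3,D:0.05):0.2);")
  set.seed(42)
  x1 <- simulateElementAlignment(tr, m, 7)
  x2 <- simulateElementAlignment(tr, m, 5)
  expect_equal(alignmentLoglik(x1[, 1, drop = FALSE], tr, m),
               columnLoglik(tr, m, x1[, 1]))
  expect_equal(alignmentLoglik(cbind(x1, x2), tr, m),
               alignmentLoglik(x1, tr, m) + alignmentLoglik(x2, tr, m),
               tolerance = 1e-10)
  # all-missing column contributes exactly 0
  gap <- matrix("-", 4, 1, dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(alignmentLoglik(gap, tr, m), 0, tolerance = 1e-12)
  # species absent from the matrix are marginalised out
  expect_equal(alignmentLoglik(x1[c("A", "B"), , drop = FALSE], tr, m),
               alignmentLoglik(rbind(x1[c("A", "B"), ],
                                     C = rep("N", 7), D = rep("-", 7)),
                               tr, m), tolerance = 1e-12)
  expect_error(alignmentLoglik(x1[, 0], tr, m), "empty")
  expect_error(alignmentLoglik(rbind(x1, Z = rep("A", 7)), tr, m),
               "not in tree")
})

test_that("likelihood is invariant to re-rooting and global scaling", {
  m <- hky85(c(0.28, 0.22, 0.22, 0.28), kappa = 3)
  tr <- randomTree(6, seed = 7)
  set.seed(8)
  x <- simulateElementAlignment(tr, m, 20)
  base <- alignmentLoglik(x, tr, m)
  for (node in c("t2", "t5")) {
    rerooted <- ape::root(tr, outgroup = node, resolve.root = TRUE)
    expect_equal(alignmentLoglik(x, rerooted, m), base, tolerance = 1e-9)
  }
  # scaling every branch by c equals the scale argument
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 1.7
  expect_equal(alignmentLoglik(x, tr2, m),
               alignmentLoglik(x, tr, m, scale = 1.7), tolerance = 1e-12)
  # named per-branch scales override the default
  expect_equal(alignmentLoglik(x, tr, m, scales = c(t1 = 1)), base)
  expect_error(alignmentLoglik(x, tr, m, scales = c(zz = 2)),
               "unknown branch")
})

test_that("HKY estimation recovers kappa from simulated columns", {
  tr <- caenoTree()
  m <- hky85(c(0.3, 0.2, 0.2, 0.3), kappa = 4)
  set.seed(21)
  x <- simulateElementAlignment(tr, m, 2000)
  fit <- estimateHky(x, tr)
  expect_gt(fit@kappa, 2.5)
  expect_lt(fit@kappa, 6)
  expect_equal(unname(fit@freqs), c(0.3, 0.2, 0.2, 0.3), tolerance = 0.05)
})
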