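test_that("LRT p-value convention and boundary cases", {
  expect_equal(lrtPvalue(0, 1), 1)
  expect_equal(lrtPvalue(0, 2), 1)
  expect_equal(lrtPvalue(2.706, 1.5),
               0.5 * stats::pchisq(2.706, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrtPvalue(2.706, 1.5), 0.05, tolerance = 1e-3)
  expect_equal(lrtPvalue(5, 1), 1)  # lambda at the boundary: p = 1
  expect_true(all(lrtPvalue(c(0.1, 10, 100), 2) > 0))
})

test_that("null and alternative fits are nested and deterministic", {
  set.seed(61)
  for (i in 1:6) {
    x <- simulateElementAlignment(testTree, testModel, 40, rho = 0.4)
    n0 <- fitNullScale(x, testTree, testModel)
    n1 <- fitAccelScale(x, testTree, testModel, testTargets)
    expect_gte(n1$lnL, n0$lnL - 1e-8)
    expect_gte(n1$lambdahat, 1)
    # determinism: identical refits
    expect_identical(fitNullScale(x, testTree, testModel), n0)
    expect_identical(fitAccelScale(x, testTree, testModel, testTargets), n1)
  }
  expect_error(fitAccelScale(
    simulateElementAlignment(testTree, testModel, 10),
    testTree, testModel, "no_such_branch"), "not in tree")
  expect_error(fitNullScale(matrix("-", 2, 3,
    dimnames = list(c("C_elegans", "C_briggsae"), NULL)),
    testTree, testModel), "no data")
})

test_that("invariant elements drive the global scale to its lower bound", {
  x <- matrix("A", 11, 1, dimnames = list(testTree$tip.label, NULL))
  n0 <- fitNullScale(x, testTree, testModel)
  expect_lt(n0$rhat, 1 / 16)  # essentially at the lower search bound
})

test_that("joint mode with one target equals single-branch mode", {
  set.seed(62)
  sl <- list(a = simulateElementAlignment(testTree, testModel, 50,
                                          rho = 0.3, lambda = 4,
                                          targets = "C_elegans"),
             b = simulateElementAlignment(testTree, testModel, 50,
                                          rho = 0.3))
  rj <- testAcceleration(sl, testTree, testModel, "C_elegans", "joint")
  rs <- testAcceleration(sl, testTree, testModel, "C_elegans", "single")
  expect_equal(rj$stat, rs$stat)
  expect_equal(rj$p, rs$p)
  expect_error(testAcceleration(sl, testTree, testModel,
                                c("C_elegans", "C_briggsae"), "single"),
               "single mode")
})

test_that("planted acceleration is detected and grows with lambda", {
  set.seed(63)
  n <- 25
  hits <- vapply(seq_len(n), function(i) {
    x <- simulateElementAlignment(testTree, testModel, 60, rho = 0.3,
                                  lambda = 5, targets = "C_elegans")
    r <- testAcceleration(list(e = x), testTree, testModel,
                          "C_elegans", "single")
    r$lambdahat[1] > 1 && r$stat[1] > 0
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  medstat <- vapply(c(1, 2, 4, 8), function(lam) {
    stats::median(vapply(1:12, function(i) {
      x <- simulateElementAlignment(testTree, testModel, 60, rho = 0.3,
                                    lambda = lam, targets = testTargets)
      testAcceleration(list(e = x), testTree, testModel,
                       testTargets, "joint")$stat[1]
    }, 0))
  }, 0)
  expect_true(all(diff(medstat) >= 0))
})

test_that("global-scale recovery on simulated elements", {
  set.seed(64)
  rhats <- vapply(1:10, function(i) {
    x <- simulateElementAlignment(testTree, testModel, 200, rho = 0.5)
    fitNullScale(x, testTree, testModel)$rhat
  }, 0)
  expect_gte(mean(rhats >= 0.35 & rhats <= 0.65), 0.9)
})

test_that("FDR calling and per-species summaries follow set algebra", {
  res <- S4Vectors::DataFrame(id = sprintf("c%d", 1:4), p = rep(1, 4))
  expect_length(callAcceleratedCnes(res), 0)

  p10 <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.04, 0.2, 0.5, 0.8, 1)
  byHand <- rev(cummin(rev(p10 * 10 / seq_len(10))))
  expect_equal(stats::p.adjust(p10, "BH"), pmin(byHand, 1))

  mk <- function(ids, sig) S4Vectors::DataFrame(
    id = ids, p = ifelse(sig, 1e-6, 1))
  rl <- list(
    C_elegans = mk(sprintf("c%d", 1:6), c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    C_briggsae = mk(sprintf("c%d", 1:6), c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    C_tropicalis = mk(sprintf("c%d", 1:6), c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)))
  ps <- perSpeciesAccelerated(rl)
  expect_equal(ps$sets$C_elegans, c("c1", "c2"))
  expect_equal(ps$pairwise["C_elegans", "C_briggsae"], 1L)
  expect_equal(ps$pairwise["C_elegans", "C_tropicalis"], 0L)
  expect_length(ps$all, 0)
  # union contains every per-species set
  u <- Reduce(union, ps$sets)
  for (s in ps$sets) expect_true(all(s %in% u))
})

test_that("convergent orthogroups require different elements in >= 2 species", {
  ng <- list(A = c(c1 = "gX", c2 = "gY"),
             B = c(c3 = "gXb", c2 = "gZ"),
             C = c(c4 = "gW"))
  og <- c(gX = "OG1", gXb = "OG1", gY = "OG2", gZ = "OG3", gW = "OG4")
  # different CNEs (c1 in A, c3 in B) hit OG1 -> reported
  out <- convergentOrthogroups(list(A = "c1", B = "c3"), ng, og)
  expect_equal(out$orthogroup, "OG1")
  expect_equal(out$nSpecies, 2L)

  # the same CNE in both species is excluded
  og2 <- c(gY = "OG9", gZ = "OG9")
  out2 <- convergentOrthogroups(list(A = "c2", B = "c2"), ng, og2)
  expect_equal(nrow(out2), 0L)

  # gene missing from the map becomes a logged singleton
  expect_message(
    out3 <- convergentOrthogroups(list(A = "c1", C = "c4"), ng,
                                  c(gX = "OG1")),
    "singleton")
  expect_equal(nrow(out3), 0L)

  # planted truth: exactly the planted groups are reported
  accel <- list(A = c("e1", "e2"), B = c("e3", "e4"), C = c("e5"))
  ngm <- list(A = c(e1 = "a1", e2 = "a2"),
              B = c(e3 = "b1", e4 = "b2"),
              C = c(e5 = "c1"))
  ogm <- c(a1 = "G1", b1 = "G1", a2 = "G2", c1 = "G2", b2 = "G3")
  out4 <- convergentOrthogroups(accel, ngm, ogm)
  expect_setequal(out4$orthogroup, c("G1", "G2"))
})
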