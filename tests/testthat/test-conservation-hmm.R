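test_that("transition derivation matches the coverage parameterisation", {
  tr <- deriveTransitions(12, 0.3)
  expect_equal(unname(tr["mu"]), 1 / 12)
  expect_equal(unname(tr["nu"]), (1 / 12) * 0.3 / 0.7)
  expect_equal(unname(tr["nu"] / sum(tr)), 0.3)  # stationary coverage

  tr2 <- deriveTransitions(2, 0.5)
  expect_equal(unname(tr2), c(0.5, 0.5))

  expect_error(deriveTransitions(1, 0.3), "omega")
  expect_error(deriveTransitions(12, 1), "gamma")

  # geometric dwell time in the conserved state has mean omega
  set.seed(14)
  dwell <- stats::rgeom(2e5, prob = tr["mu"]) + 1
  expect_equal(mean(dwell), 12, tolerance = 0.02)
})

test_that("emission tracks behave as slower/faster clocks", {
  x <- matrix(rep("A", 11), ncol = 1,
              dimnames = list(testTree$tip.label, NULL))
  em <- emissionLogliks(x, testTree, testModel, rho = 0.3)
  # identical column: the slower clock explains identity better
  expect_gt(em["conserved", 1], em["nonconserved", 1])

  xdiv <- x
  xdiv[1:4, 1] <- c("A", "C", "G", "T")
  emdiv <- emissionLogliks(xdiv, testTree, testModel, rho = 0.3)
  expect_lt(emdiv["conserved", 1], emdiv["nonconserved", 1])

  # rho = 1 makes the two states indistinguishable
  em1 <- emissionLogliks(xdiv, testTree, testModel, rho = 1)
  expect_equal(unname(em1["conserved", ]), unname(em1["nonconserved", ]))
  expect_error(emissionLogliks(x, testTree, testModel, rho = 1.2), "rho")
})

test_that("forward algorithm matches exhaustive path enumeration", {
  tr <- deriveTransitions(12, 0.3)
  # single column with equal emissions: total probability is the emission
  e <- matrix(c(-1.3, -1.3), 2, 1)
  expect_equal(forwardLoglik(e, tr["mu"], tr["nu"]), -1.3)

  set.seed(31)
  for (i in 1:5) {
    L <- sample(2:8, 1)
    em <- matrix(log(stats::runif(2 * L)), 2, L)
    expect_equal(forwardLoglik(em, tr["mu"], tr["nu"]),
                 bruteForwardLoglik(em, tr["mu"], tr["nu"]),
                 tolerance = 1e-10)
  }

  # monotone in the conserved emissions
  em <- matrix(log(stats::runif(16)), 2, 8)
  lls <- vapply(seq(0, 1, by = 0.25), function(b) {
    em2 <- em; em2[1, ] <- em[1, ] + b
    forwardLoglik(em2, tr["mu"], tr["nu"])
  }, 0)
  expect_true(all(diff(lls) > 0))
})

test_that("posterior probabilities are proper and Viterbi is optimal", {
  tr <- deriveTransitions(12, 0.3)
  set.seed(32)
  em <- matrix(log(stats::runif(20)), 2, 10)
  post <- posteriorDecode(em, tr["mu"], tr["nu"])
  expect_lt(max(abs(colSums(post) - 1)), 1e-12)

  for (i in 1:4) {
    L <- sample(3:10, 1)
    em <- matrix(log(stats::runif(2 * L)), 2, L)
    path <- CNEaccel:::.viterbiPath(em, tr["mu"], tr["nu"])
    expect_equal(attr(path, "score"),
                 bruteViterbiScore(em, tr["mu"], tr["nu"]),
                 tolerance = 1e-10)
  }
})

test_that("segment calling is conservative on flat emissions and finds planted signal", {
  tr <- deriveTransitions(12, 0.3)
  # equal emissions: the all-nonconserved path wins (nu < mu at gamma 0.3)
  segs <- viterbiSegments(matrix(0, 2, 5), tr["mu"], tr["nu"], refPos = 0:4)
  expect_length(segs, 0)

  # strong 20-column stretch; background mildly favors nonconserved
  # (a flat background would make an all-conserved prefix optimal)
  em <- matrix(0, 2, 60)
  em[1, ] <- -0.5
  em[1, 21:40] <- 2; em[2, 21:40] <- -2
  segs <- viterbiSegments(em, tr["mu"], tr["nu"], refPos = 0:59,
                          chrom = "chrT")
  expect_length(segs, 1)
  expect_equal(GenomicRanges::start(segs), 21)
  expect_equal(GenomicRanges::end(segs), 40)
  expect_gt(segs$meanPosterior, 0.9)
  expect_equal(segs$score, sum(em[1, 21:40] - em[2, 21:40]))
})

test_that("rho estimation recovers the conserved scale", {
  tr <- deriveTransitions(12, 0.3)
  # degenerate grid returns the constrained optimum
  blocks <- list(matrix("A", 2, 3,
                        dimnames = list(c("C_elegans", "C_briggsae"), NULL)))
  expect_equal(estimateRho(blocks, testTree, testModel,
                           tr["mu"], tr["nu"], grid = 0.42), 0.42)
  expect_error(estimateRho(list(matrix("-", 2, 3,
      dimnames = list(c("C_elegans", "C_briggsae"), NULL))),
      testTree, testModel, tr["mu"], tr["nu"]), "all-missing")

  set.seed(33)
  mk <- function(rho) lapply(1:8, function(i) cbind(
    simulateElementAlignment(testTree, testModel, 40),
    simulateElementAlignment(testTree, testModel, 30, rho = rho),
    simulateElementAlignment(testTree, testModel, 40)))
  rhat <- estimateRho(mk(0.3), testTree, testModel, tr["mu"], tr["nu"])
  expect_gt(rhat, 0.2); expect_lt(rhat, 0.4)

  # purely neutral data: profile flat near 1
  blocksN <- lapply(1:5, function(i)
    simulateElementAlignment(testTree, testModel, 120))
  expect_gte(estimateRho(blocksN, testTree, testModel, tr["mu"], tr["nu"]),
             0.8)
})

test_that("alignment scan produces reference-coordinate segments", {
  cfg <- simConfig(seed = 77, refLength = 4000, nCne = 8,
                   cdsFraction = 0.1, accelFraction = 0)
  sim <- simulateAlignment(cfg)
  segs <- scanConservedElements(sim$maf, testTree, testModel, rho = 0.3)
  expect_s4_class(segs, "GRanges")
  expect_gt(length(segs), 0)
  truth <- GenomicRanges::reduce(c(GenomicRanges::granges(sim$truth),
                                   GenomicRanges::granges(sim$cds)))
  ov <- sum(GenomicRanges::width(GenomicRanges::intersect(segs, truth)))
  expect_gt(ov / sum(GenomicRanges::width(segs)), 0.8)
})
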