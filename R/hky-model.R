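#' Construct an HKY85 substitution model
#'
#' Builds the reversible HKY85 rate matrix from stationary base frequencies
#' and the transition/transversion rate ratio `kappa`, normalised so the
#' expected substitution rate at stationarity equals 1 (branch lengths are
#' then expected substitutions per site). With equal frequencies and
#' `kappa = 1` the model reduces to Jukes-Cantor.
#'
#' @param freqs Numeric vector of stationary frequencies for A, C, G, T.
#'   Recycled names are ignored; order is A, C, G, T.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return A [NucModel-class] object.
#' @examples
#' m <- hky85(c(0.3, 0.2, 0.2, 0.3), kappa = 2)
#' transitionMatrix(m, 0.1)
#' @export
hky85 <- function(freqs = c(0.25, 0.25, 0.25, 0.25), kappa = 1) {
  if (length(freqs) != 4L)
    stop("freqs must have length 4 (A, C, G, T)")
  freqs <- as.numeric(freqs)
  names(freqs) <- c("A", "C", "G", "T")
  if (any(!is.finite(freqs)) || any(freqs <= 0))
    stop("base frequencies must be finite and > 0")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("base frequencies must sum to 1")
  freqs <- freqs / sum(freqs)
  if (!is.finite(kappa) || kappa <= 0)
    stop("kappa must be finite and > 0")

  # transitions: A<->G, C<->T
  isTs <- matrix(FALSE, 4, 4, dimnames = list(names(freqs), names(freqs)))
  isTs["A", "G"] <- isTs["G", "A"] <- TRUE
  isTs["C", "T"] <- isTs["T", "C"] <- TRUE

  Q <- matrix(rep(freqs, each = 4), 4, 4,
              dimnames = list(names(freqs), names(freqs)))
  Q[isTs] <- Q[isTs] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q <- Q / rate

  # symmetrise with pi^(1/2) so the eigendecomposition is of a symmetric
  # matrix: exact detailed balance and numerically stable exponentials
  s <- sqrt(freqs)
  B <- Q * (s %o% (1 / s))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  evec <- e$vectors / s          # divides rows by s
  evecInv <- t(e$vectors) * rep(s, each = 4L)

  new("NucModel", freqs = freqs, kappa = kappa, Q = Q,
      evals = e$values, evec = evec, evecInv = evecInv)
}

#' HKY85 transition probability matrix
#'
#' Computes `P(t) = exp(Q t)` for a [NucModel-class], the probability of
#' each base substitution over a branch of length `t` expected
#' substitutions per site. Rows sum to 1 and the matrix satisfies detailed
#' balance with the model's stationary frequencies.
#'
#' @param model A [NucModel-class].
#' @param t Branch length (finite, >= 0).
#' @return A 4x4 stochastic matrix with rows/columns A, C, G, T.
#' @export
transitionMatrix <- function(model, t) {
  stopifnot(is(model, "NucModel"))
  if (!is.finite(t) || t < 0)
    stop("branch length t must be finite and non-negative")
  P <- model@evec %*% (exp(model@evals * t) * model@evecInv)
  dimnames(P) <- dimnames(model@Q)
  P
}

#' Estimate an HKY85 model from alignment columns
#'
#' Empirical stationary frequencies are taken from the observed base counts
#' and `kappa` is estimated by maximum likelihood on the supplied columns
#' under the given tree, using a coarse grid refined by golden-section
#' search. Intended for fitting the neutral model to putatively neutral
#' columns (e.g. a concatenation of background alignment).
#'
#' @param x Character matrix of aligned bases (rows = species, columns =
#'   sites); `N` and `-` are treated as missing.
#' @param tree Phylogeny (`ape::phylo`) with branch lengths.
#' @param kappaGrid Grid of kappa values to scan before refinement.
#' @param tol Absolute tolerance for the golden-section refinement.
#' @return A [NucModel-class] with the fitted frequencies and kappa.
#' @export
estimateHky <- function(x, tree, kappaGrid = c(0.5, 1, 2, 4, 8, 16),
                        tol = 1e-3) {
  bases <- toupper(as.vector(x))
  counts <- table(factor(bases, levels = c("A", "C", "G", "T")))
  if (sum(counts) == 0)
    stop("no non-missing bases to estimate frequencies from")
  freqs <- (as.numeric(counts) + 1) / (sum(counts) + 4)  # +1 pseudocount
  f <- function(k) alignmentLoglik(x, tree, hky85(freqs, k))
  ll <- vapply(kappaGrid, f, 0)
  i <- which.max(ll)
  lo <- kappaGrid[max(1L, i - 1L)]
  hi <- kappaGrid[min(length(kappaGrid), i + 1L)]
  kap <- .goldenMax(f, lo, hi, tol = tol)$x
  hky85(freqs, kap)
}

# deterministic golden-section maximisation on [lo, hi]
.goldenMax <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}
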