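#' Transition probabilities of the conservation HMM
#'
#' The two-state (conserved/nonconserved) phylogenetic HMM is parameterised
#' by the expected conserved-segment length `omega` (columns) and the target
#' coverage `gamma`, following the phastCons convention: the
#' conserved-to-nonconserved switch probability is `mu = 1/omega` and the
#' reverse switch probability `nu = mu * gamma / (1 - gamma)`, so that the
#' stationary probability of the conserved state is exactly `gamma` and the
#' mean dwell time in the conserved state is `omega` columns.
#'
#' @param omega Expected conserved-segment length in columns (> 1).
#' @param gamma Target coverage, in (0, 1).
#' @return Named numeric vector `c(mu = ..., nu = ...)`.
#' @examples
#' deriveTransitions(12, 0.3)
#' @export
deriveTransitions <- function(omega, gamma) {
  if (!is.finite(omega) || omega <= 1)
    stop("omega must be finite and > 1")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("gamma must lie in (0, 1)")
  mu <- 1 / omega
  nu <- mu * gamma / (1 - gamma)
  if (nu >= 1)
    stop("derived nu >= 1; increase omega or decrease gamma")
  c(mu = mu, nu = nu)
}

#' Per-column emission log-likelihoods of the two HMM states
#'
#' The conserved state emits columns under the phylogeny with all branch
#' lengths multiplied by `rho` (in (0, 1]); the nonconserved state uses the
#' unscaled tree. Columns where every species is missing emit log-probability
#' 0 in both states.
#'
#' @param x Character alignment matrix (rows = species).
#' @param tree Phylogeny (`ape::phylo`).
#' @param model A [NucModel-class].
#' @param rho Conserved-state branch scale in (0, 1].
#' @return 2 x L matrix with rows `conserved`, `nonconserved`.
#' @export
emissionLogliks <- function(x, tree, model, rho) {
  if (!is.finite(rho) || rho <= 0 || rho > 1)
    stop("rho must lie in (0, 1]")
  cons <- alignmentLoglik(x, tree, model, scale = rho, perColumn = TRUE)
  noncons <- alignmentLoglik(x, tree, model, perColumn = TRUE)
  rbind(conserved = cons, nonconserved = noncons)
}

#' HMM forward log-likelihood
#'
#' Total log-probability of the column emissions under the two-state chain,
#' with the initial distribution at stationarity
#' `(gamma, 1 - gamma) = (nu, mu) / (mu + nu)`.
#'
#' @param emissions 2 x L matrix of emission log-likelihoods
#'   (rows: conserved, nonconserved).
#' @param mu,nu Switch probabilities from [deriveTransitions()].
#' @return Log-likelihood of the emission sequence.
#' @export
forwardLoglik <- function(emissions, mu, nu) {
  .hmmForward(emissions, mu, nu)$loglik
}

# scaled linear-space forward pass; returns scaled alphas and per-column
# log normalisers
.hmmForward <- function(emissions, mu, nu) {
  if (!is.matrix(emissions) || nrow(emissions) != 2L || ncol(emissions) < 1L)
    stop("emissions must be a 2 x L matrix with L >= 1")
  L <- ncol(emissions)
  gamma <- nu / (mu + nu)
  # emission scaling per column
  mx <- pmax(emissions[1L, ], emissions[2L, ])
  e <- exp(emissions - rep(mx, each = 2L))
  alpha <- matrix(0, 2L, L)
  logc <- numeric(L)
  a <- c(gamma, 1 - gamma) * e[, 1L]
  s <- sum(a); alpha[, 1L] <- a / s; logc[1L] <- log(s) + mx[1L]
  if (L > 1L) {
    for (i in 2:L) {
      prev <- alpha[, i - 1L]
      a <- c(prev[1L] * (1 - mu) + prev[2L] * nu,
             prev[1L] * mu + prev[2L] * (1 - nu)) * e[, i]
      s <- sum(a)
      alpha[, i] <- a / s
      logc[i] <- log(s) + mx[i]
    }
  }
  list(alpha = alpha, logc = logc, loglik = sum(logc))
}

#' Posterior state probabilities (forward-backward)
#'
#' @inheritParams forwardLoglik
#' @return 2 x L matrix of posterior probabilities (columns sum to 1).
#' @export
posteriorDecode <- function(emissions, mu, nu) {
  fw <- .hmmForward(emissions, mu, nu)
  L <- ncol(emissions)
  mx <- pmax(emissions[1L, ], emissions[2L, ])
  e <- exp(emissions - rep(mx, each = 2L))
  beta <- matrix(0, 2L, L)
  beta[, L] <- 1
  if (L > 1L) {
    for (i in (L - 1L):1L) {
      nxt <- beta[, i + 1L] * e[, i + 1L]
      b <- c((1 - mu) * nxt[1L] + mu * nxt[2L],
             nu * nxt[1L] + (1 - nu) * nxt[2L])
      beta[, i] <- b / sum(b)
    }
  }
  post <- fw$alpha * beta
  post <- post / rep(colSums(post), each = 2L)
  rownames(post) <- c("conserved", "nonconserved")
  post
}

# Viterbi path over the two states; 1 = conserved, 2 = nonconserved.
# Ties at every comparison are resolved toward the nonconserved state so
# element calling is conservative and deterministic.
.viterbiPath <- function(emissions, mu, nu) {
  L <- ncol(emissions)
  gamma <- nu / (mu + nu)
  logT <- log(matrix(c(1 - mu, nu, mu, 1 - nu), 2L, 2L))  # [from, to]
  delta <- matrix(-Inf, 2L, L)
  back <- matrix(1L, 2L, L)
  delta[, 1L] <- log(c(gamma, 1 - gamma)) + emissions[, 1L]
  if (L > 1L) {
    for (i in 2:L) {
      for (s in 1:2) {
        cand <- delta[, i - 1L] + logT[, s]
        # tie -> come from nonconserved (state 2)
        from <- if (cand[2L] >= cand[1L]) 2L else 1L
        delta[s, i] <- cand[from] + emissions[s, i]
        back[s, i] <- from
      }
    }
  }
  path <- integer(L)
  path[L] <- if (delta[2L, L] >= delta[1L, L]) 2L else 1L
  if (L > 1L) for (i in (L - 1L):1L) path[i] <- back[path[i + 1L], i + 1L]
  attr(path, "score") <- max(delta[2L, L], delta[1L, L])
  path
}

#' Conserved segments from the Viterbi path
#'
#' Calls conserved segments as maximal runs of the conserved state on the
#' most probable state path (ties resolved toward the nonconserved state),
#' and annotates each segment with its mean posterior conserved probability
#' and its log-odds score (sum over columns of conserved minus nonconserved
#' emission log-likelihood). Columns are mapped to reference coordinates via
#' `refPos`; runs without any mapped column are dropped.
#'
#' @inheritParams forwardLoglik
#' @param refPos Integer vector (length L) of 0-based reference positions
#'   per column, `NA` for columns not present in the reference.
#' @param chrom Reference chromosome name for the returned ranges.
#' @return A `GRanges` (1-based, as usual for `GRanges`) with metadata
#'   columns `score` (log-odds) and `meanPosterior`.
#' @export
viterbiSegments <- function(emissions, mu, nu, refPos, chrom = "chr") {
  path <- .viterbiPath(emissions, mu, nu)
  post <- posteriorDecode(emissions, mu, nu)
  r <- rle(path == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- GRanges()
  if (length(keep)) {
    segs <- lapply(keep, function(k) {
      cols <- starts[k]:ends[k]
      pos <- refPos[cols]
      pos <- pos[!is.na(pos)]
      if (!length(pos)) return(NULL)
      data.frame(
        start = min(pos) + 1L, end = max(pos) + 1L,  # to 1-based closed
        score = sum(emissions[1L, cols] - emissions[2L, cols]),
        meanPosterior = mean(post[1L, cols])
      )
    })
    segs <- do.call(rbind, segs)
    if (!is.null(segs) && nrow(segs)) {
      out <- GRanges(chrom, IRanges(segs$start, segs$end),
                     score = segs$score, meanPosterior = segs$meanPosterior)
    }
  }
  out
}

#' Estimate the conserved-state branch scale rho
#'
#' Maximises the total HMM forward log-likelihood over a grid of rho values
#' in (0, 1], refined by golden-section search around the best grid point.
#' Deterministic given its inputs; rho is estimated once per dataset.
#'
#' @param blocks List of alignment matrices (rows = species).
#' @param tree,model Phylogeny and substitution model.
#' @param mu,nu HMM switch probabilities.
#' @param grid Rho grid to scan (values in (0, 1]).
#' @param tol Golden-section tolerance.
#' @return The maximising rho.
#' @export
estimateRho <- function(blocks, tree, model, mu, nu,
                        grid = seq(0.1, 1, by = 0.1), tol = 5e-3) {
  if (!length(blocks)) stop("no alignment blocks supplied")
  anyData <- any(vapply(blocks, function(b)
    any(toupper(b) %in% .BASES), TRUE))
  if (!anyData) stop("all-missing data: cannot estimate rho")
  f <- function(r) {
    sum(vapply(blocks, function(b)
      forwardLoglik(emissionLogliks(b, tree, model, r), mu, nu), 0))
  }
  if (length(grid) == 1L) return(grid)
  ll <- vapply(grid, f, 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (lo == hi) return(lo)
  .goldenMax(f, lo, hi, tol = tol)$x
}

#' Scan an alignment for conserved elements
#'
#' Runs the two-state phylogenetic HMM over every block of a reference-
#' anchored alignment and returns the conserved segments in reference
#' coordinates. Uses the phastCons parameterisation (expected length
#' `omega`, target coverage `gamma`; defaults 12 and 0.3) with conserved-
#' state branch scale `rho`.
#'
#' @param maf A [MafAlignment-class].
#' @param tree,model Phylogeny and substitution model.
#' @param omega Expected conserved-segment length (columns).
#' @param gamma Target coverage.
#' @param rho Conserved-state branch scale; if `NULL` it is estimated with
#'   [estimateRho()] on the alignment blocks.
#' @return `GRanges` of conserved segments on the reference, sorted, with
#'   `score` and `meanPosterior` metadata columns.
#' @export
scanConservedElements <- function(maf, tree, model, omega = 12, gamma = 0.3,
                                  rho = NULL) {
  stopifnot(is(maf, "MafAlignment"))
  tr <- deriveTransitions(omega, gamma)
  mats <- lapply(maf@blocks, blockMatrix)
  if (is.null(rho))
    rho <- estimateRho(mats, tree, model, tr["mu"], tr["nu"])
  segs <- lapply(seq_along(maf@blocks), function(i) {
    b <- maf@blocks[[i]]
    em <- emissionLogliks(mats[[i]], tree, model, rho)
    viterbiSegments(em, tr["mu"], tr["nu"],
                    refPos = .refCoords(b, maf@reference),
                    chrom = .srcChrom(b$src[[maf@reference]]))
  })
  out <- sort(do.call(c, segs))
  S4Vectors::metadata(out)$rho <- rho
  out
}
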