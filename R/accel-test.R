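#' Branch-targeted likelihood-ratio test for accelerated evolution
#'
#' For each element alignment, the null model fits a single free global
#' branch scale `r` (all branches multiplied by `r`); the alternative
#' additionally fits one shared acceleration scale `lambda >= 1` applied
#' multiplicatively to every target branch. Both fits use a deterministic
#' coarse log-spaced grid refined by golden-section search, so results are
#' reproducible bit-for-bit. The LRT statistic is `2 (lnL1 - lnL0)` and the
#' p-value uses the one-sided boundary mixture `0.5 chi2_0 + 0.5 chi2_1`
#' (lambda is tested at its boundary value 1).
#'
#' `fitNullScale` and `fitAccelScale` expose the two fits;
#' [testAcceleration()] runs them over a list of element alignments and
#' applies Benjamini-Hochberg correction within the run.
#'
#' @param x Character alignment matrix (rows = species).
#' @param tree,model Phylogeny and substitution model.
#' @param targets Character vector of target branch names (each the child
#'   node of the branch; a species name designates its terminal branch).
#' @param rBounds,lambdaBounds Search intervals for `r` and `lambda`.
#' @param tol Golden-section tolerance (on the log scale for `r`).
#' @return `fitNullScale`: `list(lnL, rhat)`; `fitAccelScale`:
#'   `list(lnL, rhat, lambdahat)`.
#' @export
fitNullScale <- function(x, tree, model, rBounds = c(1 / 32, 32),
                         tol = 1e-3) {
  if (!is.matrix(x) || ncol(x) == 0L || !any(toupper(x) %in% .BASES))
    stop("element alignment has no data columns")
  machine <- .pruneMachine(tree)
  parts <- .leafPartials(x, machine)
  base <- .edgeScales(machine, NULL)
  fit <- .fitR(machine, model, parts, base, rBounds, tol)
  list(lnL = fit$value, rhat = fit$x)
}

# profile optimisation of the global scale r given fixed per-branch
# multipliers `base` (Brent on the log scale after a coarse grid)
.fitR <- function(machine, model, parts, base, rBounds, tol) {
  f <- function(logr)
    .machineLoglik(machine, model, parts, base * exp(logr))
  grid <- seq(log(rBounds[1L]), log(rBounds[2L]), length.out = 7L)
  ll <- vapply(grid, f, 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective >= ll[i])
    list(x = exp(opt$maximum), value = opt$objective)
  else list(x = exp(grid[i]), value = ll[i])
}

#' @rdname fitNullScale
#' @export
fitAccelScale <- function(x, tree, model, targets,
                          rBounds = c(1 / 32, 32),
                          lambdaBounds = c(1, 64), tol = 1e-3) {
  if (!length(targets)) stop("targets must be non-empty")
  machine <- .pruneMachine(tree)
  bad <- setdiff(targets, machine$childLabel)
  if (length(bad))
    stop("target branch(es) not in tree: ", paste(bad, collapse = ", "))
  parts <- .leafPartials(x, machine)
  tIdx <- machine$childLabel %in% targets
  loglik <- function(r, lambda)
    .machineLoglik(machine, model, parts,
                   ifelse(tIdx, r * lambda, r))
  # coarse lambda grid at the null's optimal r, then coordinate descent
  # (Brent in log r and log lambda alternately); deterministic throughout
  null <- .fitR(machine, model, parts, rep(1, length(tIdx)), rBounds, tol)
  lamGrid <- c(1, 2, 4, 8, 16, 32, 64)
  lamGrid <- unique(pmin(pmax(lamGrid, lambdaBounds[1L]),
                         lambdaBounds[2L]))
  ll0 <- vapply(lamGrid, function(l) loglik(null$x, l), 0)
  lam <- lamGrid[which.max(ll0)]
  r <- null$x
  best <- max(ll0)
  for (it in 1:3) {
    or <- stats::optimize(function(lr) loglik(exp(lr), lam),
                          log(rBounds), maximum = TRUE, tol = tol)
    if (or$objective > best) { r <- exp(or$maximum); best <- or$objective }
    ol <- stats::optimize(function(ll_) loglik(r, exp(ll_)),
                          log(lambdaBounds), maximum = TRUE, tol = tol)
    if (ol$objective > best) { lam <- exp(ol$maximum); best <- ol$objective }
  }
  # the boundary lambda = 1 must remain admissible
  if (null$value >= best)
    list(lnL = null$value, rhat = null$x, lambdahat = 1)
  else list(lnL = best, rhat = r, lambdahat = lam)
}

#' P-value of the acceleration LRT
#'
#' One-sided boundary-corrected p-value: `0.5 * P(chi2_1 >= statistic)`
#' when the fitted acceleration scale exceeds 1, else 1.
#'
#' @param statistic LRT statistic `2 (lnL1 - lnL0)` (>= 0).
#' @param lambdahat Fitted acceleration scale.
#' @return P-value in (0, 1].
#' @export
lrtPvalue <- function(statistic, lambdahat) {
  statistic <- pmax(statistic, 0)
  p <- ifelse(lambdahat > 1 + 1e-8 & statistic > 0,
              0.5 * stats::pchisq(statistic, df = 1, lower.tail = FALSE),
              1)
  pmin(p, 1)
}

#' Run the acceleration test over a CNE catalog
#'
#' Applies the branch-targeted LRT to each element alignment slice. In
#' `joint` mode one shared lambda is fitted across all target branches (the
#' design used to call elements accelerated on all hermaphrodite branches
#' in the same run); `single` mode expects a single target branch. The
#' boundary fit at `lambda = 1` reuses the null optimisation, so
#' `lnL1 >= lnL0` holds by construction.
#'
#' @param slices Named list of element alignment matrices (see
#'   [sliceAlignment()]).
#' @param tree,model Phylogeny and substitution model.
#' @param targets Target branch names.
#' @param mode `"joint"` (shared lambda over the target set) or `"single"`
#'   (one target branch). With one target the two modes are identical.
#' @inheritParams fitNullScale
#' @return `DataFrame` with one row per element: `id`, `lnL0`, `lnL1`,
#'   `rhat`, `lambdahat`, `stat`, `p`, `q` (BH within this run).
#' @export
testAcceleration <- function(slices, tree, model, targets,
                             mode = c("joint", "single"),
                             rBounds = c(1 / 32, 32),
                             lambdaBounds = c(1, 64), tol = 1e-3) {
  mode <- match.arg(mode)
  if (mode == "single" && length(targets) != 1L)
    stop("single mode requires exactly one target branch")
  ids <- names(slices)
  if (is.null(ids)) ids <- as.character(seq_along(slices))
  rows <- lapply(seq_along(slices), function(i) {
    x <- slices[[i]]
    if (!is.matrix(x) || ncol(x) == 0L || !any(toupper(x) %in% .BASES))
      return(DataFrame(id = ids[i], lnL0 = NA_real_, lnL1 = NA_real_,
                       rhat = NA_real_, lambdahat = NA_real_,
                       stat = NA_real_, p = NA_real_))
    n0 <- fitNullScale(x, tree, model, rBounds, tol)
    n1 <- fitAccelScale(x, tree, model, targets, rBounds, lambdaBounds, tol)
    if (n1$lnL < n0$lnL) {  # boundary: lambda = 1 is the optimum
      n1 <- list(lnL = n0$lnL, rhat = n0$rhat, lambdahat = 1)
    }
    stat <- max(0, 2 * (n1$lnL - n0$lnL))
    DataFrame(id = ids[i], lnL0 = n0$lnL, lnL1 = n1$lnL, rhat = n1$rhat,
              lambdahat = n1$lambdahat, stat = stat,
              p = lrtPvalue(stat, n1$lambdahat))
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Call accelerated elements at an FDR threshold
#'
#' Benjamini-Hochberg over all tested elements of one run; elements with
#' `q < alpha` are called accelerated.
#'
#' @param results Output of [testAcceleration()].
#' @param alpha FDR threshold (default 0.05).
#' @return Character vector of accelerated element ids.
#' @export
callAcceleratedCnes <- function(results, alpha = 0.05) {
  q <- stats::p.adjust(results$p, method = "BH")
  results$id[!is.na(q) & q < alpha]
}

#' Per-species accelerated sets and their intersections
#'
#' Summarises single-branch runs for several species: the per-species
#' accelerated sets (q < alpha within each species' run) and the pairwise
#' and triple intersection counts.
#'
#' @param resultsList Named list (by species) of [testAcceleration()]
#'   outputs from single-branch runs.
#' @param alpha FDR threshold.
#' @return List with `sets` (per-species id vectors), `pairwise` (matrix of
#'   intersection counts) and `all` (ids accelerated in every species).
#' @export
perSpeciesAccelerated <- function(resultsList, alpha = 0.05) {
  sets <- lapply(resultsList, callAcceleratedCnes, alpha = alpha)
  sp <- names(sets)
  pw <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) for (j in seq_along(sp))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  list(sets = sets, pairwise = pw, all = Reduce(intersect, sets))
}

#' Orthogroups hit convergently by different accelerated CNEs
#'
#' An orthogroup qualifies when, in at least two species, some
#' species-accelerated CNE has its nearest gene in that group and the
#' contributing CNEs are not all the same element (independent hits).
#' Genes absent from the orthogroup map are treated as their own singleton
#' group (logged via `message`).
#'
#' @param accelSets Named list (per species) of accelerated CNE ids.
#' @param nearestGenes Named list (per species) of named character vectors
#'   mapping CNE id to nearest gene id.
#' @param orthogroups Named character vector mapping gene id to orthogroup
#'   id.
#' @return `DataFrame` of qualifying orthogroups with the contributing
#'   species and CNE ids.
#' @export
convergentOrthogroups <- function(accelSets, nearestGenes, orthogroups) {
  contrib <- list()  # group -> species -> cne ids
  nSingleton <- 0L
  for (sp in names(accelSets)) {
    ng <- nearestGenes[[sp]]
    for (cne in accelSets[[sp]]) {
      gene <- ng[[cne]]
      if (is.null(gene) || is.na(gene)) next
      grp <- orthogroups[gene]
      if (is.na(grp)) {
        grp <- paste0("singleton:", gene)
        nSingleton <- nSingleton + 1L
      }
      contrib[[grp]][[sp]] <- union(contrib[[grp]][[sp]], cne)
    }
  }
  if (nSingleton)
    message(nSingleton, " accelerated-CNE gene(s) missing from the ",
            "orthogroup map; counted as singleton groups")
  rows <- lapply(names(contrib), function(grp) {
    bySp <- contrib[[grp]]
    if (length(bySp) < 2L) return(NULL)
    # require two species whose contributing CNEs are not the same element
    distinct <- FALSE
    sp <- names(bySp)
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      if (i < j && length(union(bySp[[i]], bySp[[j]])) > 1L)
        distinct <- TRUE
    }
    if (!distinct) return(NULL)
    DataFrame(orthogroup = grp,
              nSpecies = length(bySp),
              species = paste(sp, collapse = ","),
              cnes = paste(unlist(lapply(sp, function(s)
                paste0(s, ":", bySp[[s]]))), collapse = ";"))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(DataFrame(orthogroup = character(0), nSpecies = integer(0),
                     species = character(0), cnes = character(0)))
  do.call(rbind, rows)
}
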