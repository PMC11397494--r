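#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of aligned columns under an HKY85 model on a
#' rooted tree, marginalising over internal states with the pruning
#' algorithm. `N` and `-` are treated as missing data (partial vector of
#' ones), so a fully missing column contributes exactly 0. Per-branch rate
#' scaling is supported through `scales` (a named vector, names = the child
#' node of the scaled branch) on top of a global multiplier `scale`; branch
#' lengths are multiplied by their scale before matrix exponentiation.
#' Numerical underflow on long elements is handled by per-node rescaling of
#' the partial vectors with accumulated log-scalers, so the returned log
#' value is exact to machine precision.
#'
#' @param x Character matrix of aligned symbols in \{A,C,G,T,N,-\}; rows
#'   named by species (a subset of the tree's leaves — leaves without a row
#'   are treated as missing), columns are sites.
#' @param tree Phylogeny (`ape::phylo`, rooted, with branch lengths).
#' @param model A [NucModel-class].
#' @param scales Optional named numeric vector of per-branch scale factors
#'   (default 1 for unlisted branches).
#' @param scale Global branch-scale multiplier applied to every branch.
#' @param perColumn If `TRUE`, return the per-column log-likelihood vector
#'   instead of the sum.
#' @return Total log-likelihood (or per-column vector).
#' @examples
#' tr <- readSpeciesTree("(A:0.1,B:0.2);")
#' m <- hky85()
#' alignmentLoglik(rbind(A = c("A", "C"), B = c("A", "T")), tr, m)
#' @export
alignmentLoglik <- function(x, tree, model, scales = NULL, scale = 1,
                            perColumn = FALSE) {
  if (!is.matrix(x) || ncol(x) == 0L)
    stop("empty alignment block")
  machine <- .pruneMachine(tree)
  bad <- setdiff(rownames(x), machine$tips)
  if (length(bad))
    stop("species not in tree: ", paste(bad, collapse = ", "))
  parts <- .leafPartials(x, machine)
  es <- .edgeScales(machine, scales) * scale
  .machineLoglik(machine, model, parts, es, perColumn = perColumn)
}

#' Log-likelihood of a single alignment column
#'
#' @param column Named character vector mapping every tree leaf to a symbol
#'   in \{A,C,G,T,N,-\}.
#' @inheritParams alignmentLoglik
#' @return The column log-probability (<= 0 up to rounding).
#' @rdname alignmentLoglik
#' @export
columnLoglik <- function(tree, model, column, scales = NULL, scale = 1) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(column))
  if (length(missing))
    stop("column lacks a symbol for leaf/leaves: ",
         paste(missing, collapse = ", "))
  x <- matrix(column[tips], ncol = 1L, dimnames = list(tips, NULL))
  alignmentLoglik(x, tree, model, scales = scales, scale = scale)
}

# ---- internals ----------------------------------------------------------

.BASES <- c("A", "C", "G", "T")

# 4 x L conditional-likelihood matrix per tree tip; tips without an
# alignment row are fully missing (all-ones)
.leafPartials <- function(x, machine) {
  L <- ncol(x)
  ones <- matrix(1, 4L, L)
  parts <- vector("list", machine$ntip)
  for (i in seq_len(machine$ntip)) {
    sp <- machine$tips[i]
    if (!sp %in% rownames(x)) {
      parts[[i]] <- ones
      next
    }
    sym <- toupper(x[sp, ])
    idx <- match(sym, .BASES)
    unknown <- is.na(idx) & !sym %in% c("N", "-", "?")
    if (any(unknown))
      stop("unknown alignment symbol(s) for ", sp, ": ",
           paste(unique(sym[unknown]), collapse = ", "))
    m <- matrix(0, 4L, L)
    obs <- which(!is.na(idx))
    m[cbind(idx[obs], obs)] <- 1
    miss <- which(is.na(idx))
    if (length(miss)) m[, miss] <- 1
    parts[[i]] <- m
  }
  parts
}

# Pruning over the precomputed postorder machine. `parts` holds tip
# partials; `edgeScales` is parallel to the machine's edge rows.
.machineLoglik <- function(machine, model, parts, edgeScales,
                           perColumn = FALSE) {
  L <- ncol(parts[[1L]])
  nn <- machine$ntip + machine$nnode
  partial <- vector("list", nn)
  partial[seq_len(machine$ntip)] <- parts
  logscale <- numeric(L)
  edge <- machine$edge
  lens <- machine$lengths * edgeScales
  evec <- model@evec; evecInv <- model@evecInv; evals <- model@evals
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- evec %*% (exp(evals * lens[e]) * evecInv)
    P[P < 0] <- 0
    contrib <- P %*% partial[[ch]]
    cur <- partial[[par]]
    cur <- if (is.null(cur)) contrib else cur * contrib
    m <- pmax(cur[1L, ], cur[2L, ], cur[3L, ], cur[4L, ])
    logscale <- logscale + log(m)
    m[m == 0] <- 1
    partial[[par]] <- cur / rep(m, each = 4L)
  }
  lik <- colSums(partial[[machine$root]] * model@freqs)
  ll <- log(lik) + logscale
  if (perColumn) ll else sum(ll)
}
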