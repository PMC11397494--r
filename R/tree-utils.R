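#' Read and write species trees
#'
#' Thin wrappers around `ape::read.tree()` / `ape::write.tree()` that add
#' the validation this pipeline needs: a single root, unique leaf labels,
#' and finite non-negative branch lengths on every non-root edge. The
#' round trip `readSpeciesTree(writeSpeciesTree(tree))` preserves topology
#' and branch lengths.
#'
#' @param text Newick string (alternatively use `file`).
#' @param file Path to a Newick file.
#' @param tree An `ape::phylo` object.
#' @return `readSpeciesTree` returns an `ape::phylo`; `writeSpeciesTree`
#'   returns a Newick string.
#' @examples
#' tr <- readSpeciesTree("((A:0.1,B:0.1):0.2,C:0.3);")
#' writeSpeciesTree(tr)
#' @export
readSpeciesTree <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(text)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  } else {
    ape::read.tree(file = file)
  }
  if (is.null(tr))
    stop("malformed Newick: could not parse tree")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tr
}

#' @rdname readSpeciesTree
#' @export
writeSpeciesTree <- function(tree) {
  ape::write.tree(tree)
}

#' The packaged 11-taxon Caenorhabditis tree
#'
#' A rooted 11-species tree whose clade structure follows the accepted
#' Caenorhabditis relationships, with C. niphades as the outgroup/reference
#' and the three androdioecious (hermaphroditic) species on terminal
#' branches. Branch lengths (expected substitutions per site) are round
#' numbers chosen for simulation power, not empirical estimates.
#'
#' @return An `ape::phylo` with 11 tips.
#' @examples
#' tr <- caenoTree()
#' hermaphroditeSpecies()
#' @export
caenoTree <- function() {
  readSpeciesTree(paste0(
    "(C_niphades:0.40,(C_sp44:0.35,(C_tropicalis:0.30,((C_wallacei:0.25,",
    "(C_remanei:0.10,C_latens:0.10):0.10):0.05,(C_sinica:0.22,",
    "((C_briggsae:0.15,C_nigoni:0.12):0.08,",
    "(C_elegans:0.14,C_inopinata:0.12):0.08):0.05):0.05):0.05):0.05):0.05);"
  ))
}

#' @rdname caenoTree
#' @export
hermaphroditeSpecies <- function() {
  c("C_elegans", "C_briggsae", "C_tropicalis")
}

# ---- internal tree machinery -------------------------------------------

# Precompute the postorder traversal structure used by the pruning
# likelihood: edges in postorder, child labels (tip labels; internal nodes
# get node.label or "node<N>"), and the root id.
.pruneMachine <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  child <- tr$edge[, 2L]
  nodeLab <- tr$node.label
  childLabel <- ifelse(
    child <= ntip,
    tr$tip.label[pmin(child, ntip)],
    if (!is.null(nodeLab) && length(nodeLab)) {
      lab <- nodeLab[child - ntip]
      ifelse(!is.na(lab) & nzchar(lab), lab, paste0("node", child))
    } else paste0("node", child)
  )
  list(
    ntip = ntip,
    nnode = tr$Nnode,
    root = ntip + 1L,
    edge = tr$edge,
    lengths = tr$edge.length,
    childLabel = childLabel,
    tips = tr$tip.label
  )
}

# Per-edge scale vector from a named scale map (names = child labels of the
# scaled branches); unlisted branches get `default`.
.edgeScales <- function(machine, scales = NULL, default = 1) {
  out <- rep(default, nrow(machine$edge))
  if (!is.null(scales) && length(scales)) {
    if (is.null(names(scales)))
      stop("branch scales must be named by the branch's child node")
    bad <- setdiff(names(scales), machine$childLabel)
    if (length(bad))
      stop("unknown branch name(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(scales)) || any(scales < 0))
      stop("branch scales must be finite and non-negative")
    idx <- match(names(scales), machine$childLabel)
    out[idx] <- scales
  }
  out
}
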