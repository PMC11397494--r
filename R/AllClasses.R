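#' Nucleotide substitution model (HKY85)
#'
#' An HKY85 model: stationary base frequencies over \{A,C,G,T\} and a
#' transition/transversion rate ratio kappa. The rate matrix is normalised so
#' that the expected substitution rate at stationarity is 1, which makes
#' branch lengths interpretable as expected substitutions per site. The
#' symmetrised eigendecomposition of the rate matrix is cached so transition
#' matrices can be computed quickly and with exact detailed balance.
#'
#' @slot freqs Named numeric vector of stationary frequencies (A, C, G, T).
#' @slot kappa Transition/transversion rate ratio (> 0).
#' @slot Q Normalised 4x4 rate matrix (rows sum to 0).
#' @slot evals,evec,evecInv Cached eigendecomposition of `Q`.
#'
#' @seealso [hky85()], [transitionMatrix()]
#' @exportClass NucModel
setClass("NucModel",
  representation(
    freqs = "numeric",
    kappa = "numeric",
    Q = "matrix",
    evals = "numeric",
    evec = "matrix",
    evecInv = "matrix"
  )
)

setValidity("NucModel", function(object) {
  msg <- character(0)
  f <- object@freqs
  if (length(f) != 4L || !identical(names(f), c("A", "C", "G", "T")))
    msg <- c(msg, "freqs must be a named vector over A, C, G, T (in order)")
  if (any(!is.finite(f)) || any(f <= 0))
    msg <- c(msg, "all base frequencies must be finite and > 0")
  if (abs(sum(f) - 1) > 1e-12)
    msg <- c(msg, "base frequencies must sum to 1 (within 1e-12)")
  if (!is.finite(object@kappa) || object@kappa <= 0)
    msg <- c(msg, "kappa must be finite and > 0")
  if (length(msg) == 0 && max(abs(rowSums(object@Q))) > 1e-12)
    msg <- c(msg, "rate matrix rows must sum to 0")
  if (length(msg) == 0) {
    rate <- -sum(f * diag(object@Q))
    if (abs(rate - 1) > 1e-9)
      msg <- c(msg, "rate matrix must be normalised to unit expected rate")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "NucModel", function(object) {
  cat("HKY85 nucleotide model\n")
  cat("  base frequencies:",
      paste(sprintf("%s=%.4f", names(object@freqs), object@freqs),
            collapse = " "), "\n")
  cat(sprintf("  kappa (ts/tv rate ratio): %.4f\n", object@kappa))
})

#' Reference-anchored multiple alignment (MAF blocks)
#'
#' A set of alignment blocks read from (or destined for) a MAF file. Every
#' block carries, per species, the source sequence name, 0-based start,
#' ungapped size, strand and source length, plus the gapped alignment row.
#' One species is designated the reference; its row anchors all blocks to
#' reference coordinates.
#'
#' @slot blocks List of blocks. Each block is a list with named elements
#'   `src`, `start`, `size`, `strand`, `srcSize` (all named by species) and
#'   `seq` (named character vector of gapped rows of equal width).
#' @slot reference Species name anchoring the alignment.
#'
#' @seealso [readMaf()], [writeMaf()], [blockMatrix()]
#' @exportClass MafAlignment
setClass("MafAlignment",
  representation(blocks = "list", reference = "character")
)

setValidity("MafAlignment", function(object) {
  if (length(object@reference) != 1L)
    return("reference must be a single species name")
  for (b in object@blocks) {
    if (!object@reference %in% names(b$seq))
      return("every block must contain a row for the reference species")
    if (length(unique(nchar(b$seq))) != 1L)
      return("all rows of a block must have equal (gapped) width")
  }
  TRUE
})

setMethod("show", "MafAlignment", function(object) {
  nb <- length(object@blocks)
  sp <- mafSpecies(object)
  cols <- sum(vapply(object@blocks, function(b) nchar(b$seq[[1L]]), 0))
  cat(sprintf("MafAlignment: %d block(s), %d columns, %d species (reference: %s)\n",
              nb, cols, length(sp), object@reference))
})

#' Catalog of conserved noncoding elements
#'
#' The pipeline's central entity: conserved noncoding elements (CNEs) on the
#' reference genome, their projections onto each subject species through the
#' alignment, and the per-species filter status. A species projection is
#' dropped when it aligns redundantly (splits into two or more genomic
#' intervals) or when it is more than twice as long as the reference element;
#' the reference record itself is never dropped by these rules.
#'
#' @slot ranges `GRanges` of reference-coordinate CNEs; `mcols(ranges)$id`
#'   holds the element identifiers.
#' @slot refSpecies Reference species name.
#' @slot projections Named list (one entry per non-reference species) of
#'   `GRangesList` objects parallel to `ranges`: the projected interval(s)
#'   of each element in that species (empty when unaligned).
#' @slot status Character matrix (species x element) with values
#'   `kept`, `dropped_redundant`, `dropped_length_ratio`, `unaligned`.
#'
#' @seealso [buildCneCatalog()], [cneRanges()], [cneStatus()], [keptCnes()]
#' @exportClass CneCatalog
setClass("CneCatalog",
  representation(
    ranges = "GRanges",
    refSpecies = "character",
    projections = "list",
    status = "matrix"
  )
)

setValidity("CneCatalog", function(object) {
  n <- length(object@ranges)
  if (is.null(mcols(object@ranges)$id))
    return("ranges must carry an 'id' metadata column")
  if (anyDuplicated(mcols(object@ranges)$id))
    return("element ids must be unique")
  if (n > 0 && ncol(object@status) != n)
    return("status matrix must have one column per element")
  ok <- c("kept", "dropped_redundant", "dropped_length_ratio", "unaligned")
  if (length(object@status) && !all(object@status %in% ok))
    return(sprintf("status values must be in {%s}", paste(ok, collapse = ", ")))
  TRUE
})

setMethod("show", "CneCatalog", function(object) {
  n <- length(object@ranges)
  cat(sprintf("CneCatalog: %d element(s) on reference %s\n",
              n, object@refSpecies))
  if (nrow(object@status)) {
    kept <- rowSums(object@status == "kept")
    for (sp in rownames(object@status))
      cat(sprintf("  %s: %d kept of %d\n", sp, kept[[sp]], n))
  }
})

#' Population haplotype panel
#'
#' Biallelic SNP calls over a panel of haplotypes, as parsed from a VCF.
#' Genotypes are coded 0 (reference), 1 (alternate) or NA (missing). Diploid
#' genotypes are split into two haplotypes per sample on read.
#'
#' @slot chrom Chromosome per site.
#' @slot pos 1-based position per site (strictly increasing per chromosome).
#' @slot ref,alt Reference/alternate alleles per site.
#' @slot geno Integer matrix, sites x haplotypes.
#' @slot samples Haplotype labels.
#'
#' @seealso [readHaplotypes()], [piPerElement()]
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(
    chrom = "character",
    pos = "integer",
    ref = "character",
    alt = "character",
    geno = "matrix",
    samples = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  n <- length(object@pos)
  if (length(object@chrom) != n || length(object@ref) != n ||
      length(object@alt) != n)
    return("chrom, pos, ref, alt must have one entry per site")
  if (nrow(object@geno) != n)
    return("geno must have one row per site")
  for (ch in unique(object@chrom)) {
    p <- object@pos[object@chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      return(sprintf("positions on %s must be strictly increasing", ch))
  }
  TRUE
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d biallelic site(s) x %d haplotype(s)\n",
              nrow(object@geno), ncol(object@geno)))
})
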