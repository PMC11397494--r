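#' Read population haplotypes from a VCF
#'
#' Parses a VCF into a [HaplotypePanel-class] of biallelic SNPs. Sites that
#' are not biallelic SNPs are dropped (the count is logged via `message`).
#' Haploid genotype columns contribute one haplotype per sample; diploid
#' genotypes are split at `/` or `|` into two haplotypes. Missing calls
#' (`.`) become `NA`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @return A [HaplotypePanel-class].
#' @export
readHaplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  ok <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES
  if (any(!ok))
    message(sum(!ok), " non-biallelic-SNP site(s) dropped")
  gt <- vcfR::extract.gt(v, element = "GT")[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  alleleLists <- apply(gt, 2L, strsplit, split = "[/|]")
  ploidy <- max(vapply(unlist(alleleLists, recursive = FALSE),
                       length, 0L), 1L)
  hap <- list()
  for (s in colnames(gt)) {
    al <- alleleLists[[s]]
    mat <- matrix(vapply(al, function(x) {
      x <- suppressWarnings(as.integer(x))
      length(x) <- ploidy
      x
    }, integer(ploidy)), nrow = ploidy)
    for (k in seq_len(ploidy))
      hap[[paste0(s, if (ploidy > 1L) paste0("_", k) else "")]] <- mat[k, ]
  }
  geno <- do.call(cbind, hap)
  new("HaplotypePanel",
      chrom = as.character(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = as.character(fix[, "REF"]),
      alt = as.character(fix[, "ALT"]),
      geno = geno,
      samples = colnames(geno))
}

#' Nucleotide diversity of genomic elements
#'
#' Per-element nucleotide diversity using the unbiased per-site estimator:
#' for each segregating site, `2 p (1 - p) n / (n - 1)` with `p` the
#' alternate-allele frequency among the `n` non-missing haplotypes at that
#' site (identical to the mean pairwise difference among haplotypes), summed
#' over the sites inside the element and divided by the element length.
#' Sites with fewer than two non-missing haplotypes are skipped (logged).
#' Monomorphic sites and positions without variants contribute 0.
#'
#' @param panel A [HaplotypePanel-class].
#' @param elements `GRanges` of elements.
#' @param callable Optional `GRanges` of callable regions; when supplied the
#'   denominator is the callable length inside each element instead of the
#'   full element length.
#' @return Numeric vector of per-element pi values.
#' @export
piPerElement <- function(panel, elements, callable = NULL) {
  if (any(width(elements) <= 0L)) stop("elements must have positive length")
  nOk <- rowSums(!is.na(panel@geno))
  nAlt <- rowSums(panel@geno == 1L, na.rm = TRUE)
  skip <- nOk < 2L
  if (any(skip))
    message(sum(skip), " site(s) with fewer than 2 called haplotypes skipped")
  p <- ifelse(skip, 0, nAlt / pmax(nOk, 1L))
  contrib <- ifelse(skip, 0, 2 * p * (1 - p) * nOk / pmax(nOk - 1L, 1L))
  sites <- GRanges(panel@chrom, IRanges(panel@pos, panel@pos))
  hits <- findOverlaps(sites, elements)
  total <- numeric(length(elements))
  agg <- tapply(contrib[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  total[as.integer(names(agg))] <- agg
  denom <- if (is.null(callable)) width(elements) else {
    cal <- reduce(callable)
    vapply(seq_along(elements), function(i)
      sum(width(GenomicRanges::intersect(cal, elements[i],
                                         ignore.strand = TRUE))), 0)
  }
  if (any(denom == 0))
    warning("element(s) with zero callable length yield NaN")
  total / denom
}

#' Summarise nucleotide diversity by element class
#'
#' Computes per-element pi and the per-class median, using only elements
#' strictly longer than `minLength` (default 50 bp, the rule used to avoid
#' unstable estimates from very short sequences). Classes left empty after
#' filtering are dropped (logged); classes with fewer than 10 elements are
#' flagged `lowCount`.
#'
#' @param panel A [HaplotypePanel-class].
#' @param elements `GRanges` with a `class` metadata column.
#' @param minLength Length threshold (exclusive).
#' @return List with `summary` (`DataFrame`: class, n, medianPi, lowCount)
#'   and `perElement` (`DataFrame` of element, class, width, pi).
#' @export
piByClass <- function(panel, elements, minLength = 50) {
  if (is.null(mcols(elements)$class))
    stop("elements must carry a 'class' metadata column")
  keep <- width(elements) > minLength
  dropped <- unique(mcols(elements)$class[!keep])
  elements <- elements[keep]
  if (length(elements) == 0L) stop("no elements longer than ", minLength)
  pi <- piPerElement(panel, elements)
  cls <- as.character(mcols(elements)$class)
  gone <- setdiff(dropped, cls)
  if (length(gone))
    message("class(es) empty after the >", minLength, " bp filter: ",
            paste(gone, collapse = ", "))
  ids <- mcols(elements)$id
  if (is.null(ids)) ids <- as.character(seq_along(elements))
  per <- DataFrame(id = ids, class = cls, width = width(elements), pi = pi)
  agg <- split(pi, cls)
  summary <- DataFrame(
    class = names(agg),
    n = unname(lengths(agg)),
    medianPi = unname(vapply(agg, stats::median, 0)),
    lowCount = unname(lengths(agg) < 10L)
  )
  list(summary = summary, perElement = per)
}
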