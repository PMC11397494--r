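#' Subtract coding sequence from conserved segments
#'
#' Removes every base overlapping a CDS interval from each conserved
#' segment, returning the maximal CDS-free sub-intervals of each input
#' segment (adjacent segments are never merged). All interval arithmetic is
#' on 1-based closed `GRanges`; inputs read from BED/GFF should be imported
#' with `rtracklayer`, which performs the coordinate conversion.
#'
#' @param segments `GRanges` of conserved segments on the reference.
#' @param cds `GRanges` of protein-coding (CDS) intervals on the reference.
#' @return `GRanges` of noncoding sub-intervals; `mcols()$segment` records
#'   the index of the parent segment.
#' @export
subtractCoding <- function(segments, cds) {
  if (length(segments) == 0L) return(segments)
  missingChrom <- setdiff(as.character(unique(seqnames(segments))),
                          as.character(unique(seqnames(cds))))
  if (length(missingChrom) && length(cds))
    warning("no CDS annotation on chromosome(s): ",
            paste(missingChrom, collapse = ", "),
            " - segments there pass through unsubtracted")
  strand(segments) <- "*"
  cds <- reduce(GRanges(seqnames(cds), IRanges(start(cds), end(cds))))
  hits <- findOverlaps(segments, cds)
  cdsBySeg <- GRangesList(rep(list(GRanges()), length(segments)))
  if (length(hits)) {
    cdsBySeg <- S4Vectors::split(cds[S4Vectors::subjectHits(hits)],
                                 factor(S4Vectors::queryHits(hits),
                                        levels = seq_along(segments)))
  }
  diffs <- GenomicRanges::psetdiff(segments, cdsBySeg)
  out <- unlist(diffs)
  mcols(out)$segment <- rep(seq_along(segments), lengths(diffs))
  names(out) <- NULL
  out
}

#' Apply the minimum-length rule for CNEs
#'
#' Conserved noncoding sequences are defined as CNEs only when strictly
#' longer than `minLength` bases on the reference genome (default 10 bp, so
#' an 11 bp interval is kept and a 10 bp interval is dropped).
#'
#' @param segments `GRanges` of noncoding conserved intervals.
#' @param minLength Length threshold (exclusive).
#' @return The subset with `width > minLength`.
#' @export
filterMinLength <- function(segments, minLength = 10) {
  segments[width(segments) > minLength]
}

#' Build the CNE catalog
#'
#' Turns conserved segments into the catalog of conserved noncoding
#' elements: subtracts coding sequence, applies the strict minimum-length
#' rule, assigns ids, projects each element onto every subject species
#' through the alignment, and flags per-species projections that align
#' redundantly (two or more disjoint intervals) or are more than twice as
#' long as the reference element. The reference record is never dropped by
#' these rules.
#'
#' @param segments `GRanges` of conserved segments on the reference.
#' @param cds `GRanges` of CDS intervals (or `NULL` / empty to skip
#'   subtraction, e.g. when segments are already noncoding).
#' @param maf A [MafAlignment-class] for projection.
#' @param minLength Minimum reference length (exclusive; default 10).
#' @param maxRatio Maximum projected/reference length ratio (exclusive;
#'   default 2).
#' @param idPrefix Prefix for generated element ids.
#' @return A [CneCatalog-class].
#' @export
buildCneCatalog <- function(segments, cds, maf, minLength = 10,
                            maxRatio = 2, idPrefix = "CNE") {
  noncoding <- if (!is.null(cds) && length(cds))
    subtractCoding(segments, cds) else segments
  cnes <- filterMinLength(noncoding, minLength)
  mcols(cnes) <- NULL
  mcols(cnes)$id <- sprintf("%s%05d", idPrefix, seq_along(cnes))
  species <- setdiff(mafSpecies(maf), maf@reference)
  proj <- projectToSpecies(maf, cnes, species)
  status <- matrix("unaligned", nrow = length(species), ncol = length(cnes),
                   dimnames = list(species, mcols(cnes)$id))
  for (sp in species) {
    p <- proj[[sp]]
    nint <- lengths(p)
    plen <- sum(width(p))
    status[sp, nint == 1L] <- "kept"
    status[sp, nint >= 2L] <- "dropped_redundant"
    tooLong <- nint == 1L & plen > maxRatio * width(cnes)
    status[sp, tooLong] <- "dropped_length_ratio"
  }
  new("CneCatalog", ranges = cnes, refSpecies = maf@reference,
      projections = proj, status = status)
}

#' Nearest gene for each element
#'
#' For each query interval, finds the closest gene: distance 0 when
#' overlapping, otherwise the minimal base gap. Ties are broken by leftmost
#' gene start, then lexicographically by gene id; strand is ignored. The
#' signed distance is positive when the gene lies downstream (higher
#' coordinates) of the element and negative when upstream.
#'
#' @param query `GRanges` of elements.
#' @param genes `GRanges` of gene bodies with `mcols()$gene_id`.
#' @return `DataFrame` with columns `gene_id` and `distance` (NA, with a
#'   warning, for elements on chromosomes without genes).
#' @export
nearestGene <- function(query, genes) {
  if (is.null(mcols(genes)$gene_id))
    stop("genes must carry a 'gene_id' metadata column")
  gid <- rep(NA_character_, length(query))
  gdist <- rep(NA_integer_, length(query))
  gchr <- as.character(seqnames(genes))
  for (i in seq_along(query)) {
    chr <- as.character(seqnames(query))[i]
    j <- which(gchr == chr)
    if (!length(j)) next
    qs <- start(query)[i]; qe <- end(query)[i]
    gs <- start(genes)[j]; ge <- end(genes)[j]
    d <- ifelse(gs > qe, gs - qe - 1L,         # gene downstream: +gap
         ifelse(ge < qs, -(qs - ge - 1L), 0L)) # gene upstream: -gap
    ord <- order(abs(d), gs, mcols(genes)$gene_id[j])
    best <- j[ord[1L]]
    gid[i] <- mcols(genes)$gene_id[best]
    gdist[i] <- d[ord[1L]]
  }
  if (anyNA(gid))
    warning(sum(is.na(gid)), " element(s) on chromosomes without genes")
  DataFrame(gene_id = gid, distance = gdist)
}

#' One-sided Fisher's exact p-value for 2x2 tables
#'
#' Exact hypergeometric tail probability for enrichment
#' (`alternative = "greater"`: P(X >= a) with X hypergeometric on the
#' table's margins), depletion, or the two-sided probability-mass rule.
#' Vectorised over tables for the one-sided alternatives.
#'
#' @param a,b,c,d Cell counts: rows = group 1/group 2, columns =
#'   success/failure, so `a` = group-1 successes.
#' @param alternative One of `"greater"`, `"less"`, `"two.sided"`.
#' @return P-value(s).
#' @export
fisherP <- function(a, b, c, d, alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  m <- a + b; n <- c + d; k <- a + c
  switch(alternative,
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE),
    less = stats::phyper(a, m, n, k),
    two.sided = mapply(function(a, m, n, k) {
      lo <- max(0, k - n); hi <- min(k, m)
      dens <- stats::dhyper(lo:hi, m, n, k)
      sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
    }, a, m, n, k)
  )
}

#' Annotation-overlap enrichment of accelerated elements
#'
#' For each annotation feature type, tests whether accelerated elements
#' overlap that feature class more often than the remaining elements of the
#' universe (one-sided Fisher's exact test, enrichment direction), with
#' Benjamini-Hochberg correction across feature types. The universe is the
#' full set of kept CNEs; an element overlaps a class when its reference
#' interval shares at least one base with any interval of that class.
#'
#' @param accelerated Character vector of accelerated element ids.
#' @param universe Character vector of all element ids (superset of
#'   `accelerated`).
#' @param cnes `GRanges` with `mcols()$id` covering the universe.
#' @param annotations Named list of `GRanges`, one per feature type.
#' @return `DataFrame` with one row per feature type: the 2x2 counts,
#'   sample odds ratio (0.5 added to every cell when any cell is zero),
#'   one-sided p and BH q.
#' @export
annotationEnrichment <- function(accelerated, universe, cnes, annotations) {
  if (!all(accelerated %in% universe))
    stop("accelerated ids must be a subset of the universe")
  ids <- mcols(cnes)$id
  cnes <- cnes[ids %in% universe]
  ids <- mcols(cnes)$id
  isAcc <- ids %in% accelerated
  rows <- lapply(names(annotations), function(ft) {
    ov <- IRanges::overlapsAny(cnes, annotations[[ft]])
    a <- sum(isAcc & ov); b <- sum(isAcc & !ov)
    c_ <- sum(!isAcc & ov); d <- sum(!isAcc & !ov)
    p <- if (length(accelerated) == 0L) 1 else fisherP(a, b, c_, d, "greater")
    orr <- if (any(c(a, b, c_, d) == 0L))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    DataFrame(feature = ft, accelOverlap = a, accelNo = b,
              otherOverlap = c_, otherNo = d, oddsRatio = orr, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
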