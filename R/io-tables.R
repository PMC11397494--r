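#' Write pipeline result tables
#'
#' Deterministic TSV writers for the catalog, nearest-gene, nucleotide
#' diversity and transition-table results, with fixed numeric formatting so
#' outputs are byte-stable across platforms. Coordinates are written
#' 0-based half-open (BED convention).
#'
#' @param catalog A [CneCatalog-class].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeCneCatalogTsv <- function(catalog, path) {
  gr <- cneRanges(catalog)
  st <- cneStatus(catalog)
  sp <- sort(rownames(st))
  header <- paste(c("id", "chrom", "start", "end",
                    paste0("status_", sp)), collapse = "\t")
  rows <- vapply(seq_along(gr), function(i) {
    paste(c(mcols(gr)$id[i], as.character(seqnames(gr))[i],
            start(gr)[i] - 1L, end(gr)[i], st[sp, i]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @param ids Element ids (parallel to `nearest`).
#' @param nearest Output of [nearestGene()].
#' @rdname writeCneCatalogTsv
#' @export
writeNearestGeneTsv <- function(ids, nearest, path) {
  rows <- sprintf("%s\t%s\t%d", ids, nearest$gene_id, nearest$distance)
  writeLines(c("id\tgene_id\tdistance", rows), path)
  invisible(path)
}

#' @param pi Output of [piByClass()] (its `perElement` table, which must
#'   carry an `id` column).
#' @rdname writeCneCatalogTsv
#' @export
writePiTsv <- function(pi, path) {
  per <- pi$perElement
  rows <- sprintf("%s\t%s\t%d\t%.8f", per$id, per$class, per$width, per$pi)
  writeLines(c("id\tclass\twidth\tpi", rows), path)
  invisible(path)
}

#' @param transition Output of [transitionAssociation()].
#' @rdname writeCneCatalogTsv
#' @export
writeTransitionTsv <- function(transition, path) {
  ce <- transition$cells
  rows <- sprintf("%s\t%s\t%d\t%d\t%.6g\t%.8f\t%.8f",
                  ce$classA, ce$classB, ce$n, ce$nNeighbor, ce$oddsRatio,
                  ce$p, ce$q)
  writeLines(c("classA\tclassB\tn\tnNeighbor\toddsRatio\tp\tq", rows),
             path)
  invisible(path)
}
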