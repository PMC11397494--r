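#' Read and write MAF multiple alignments
#'
#' A minimal reader/writer for the MAF (multiple alignment format) blocks
#' this pipeline consumes. Source fields of the form `species.chrom` are
#' split at the first dot into species and chromosome; coordinates follow
#' the MAF convention (0-based starts, ungapped sizes, strand-relative
#' starts for `-` strand rows).
#'
#' @param path Path to a MAF file.
#' @param reference Species name anchoring the alignment (must be present,
#'   on the `+` strand, in every block).
#' @param maf A [MafAlignment-class].
#' @return `readMaf` returns a [MafAlignment-class]; `writeMaf` writes the
#'   file and returns `path` invisibly.
#' @export
readMaf <- function(path, reference) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur$seq)) blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      blocks <- flush(cur, blocks)
      cur <- list(src = character(), start = integer(), size = integer(),
                  strand = character(), srcSize = integer(),
                  seq = character())
    } else if (startsWith(ln, "s ")) {
      if (is.null(cur)) stop("MAF 's' line before any 'a' line")
      f <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (length(f) != 7L) stop("malformed MAF 's' line: ", ln)
      sp <- sub("\\..*$", "", f[2L])
      chrom <- sub("^[^.]*\\.?", "", f[2L])
      if (!nzchar(chrom)) chrom <- f[2L]
      cur$src[sp] <- chrom
      cur$start[sp] <- as.integer(f[3L])
      cur$size[sp] <- as.integer(f[4L])
      cur$strand[sp] <- f[5L]
      cur$srcSize[sp] <- as.integer(f[6L])
      cur$seq[sp] <- f[7L]
    }
  }
  blocks <- flush(cur, blocks)
  new("MafAlignment", blocks = blocks, reference = reference)
}

#' @rdname readMaf
#' @export
writeMaf <- function(maf, path) {
  stopifnot(is(maf, "MafAlignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in maf@blocks) {
    writeLines("", con)
    writeLines("a score=0.0", con)
    for (sp in names(b$seq)) {
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         sp, b$src[[sp]], b$start[[sp]], b$size[[sp]],
                         b$strand[[sp]], b$srcSize[[sp]], b$seq[[sp]]), con)
    }
  }
  invisible(path)
}

#' Alignment block as a character matrix
#'
#' @param block One element of `MafAlignment@blocks`.
#' @return Character matrix (species x columns) of aligned symbols.
#' @export
blockMatrix <- function(block) {
  do.call(rbind, lapply(block$seq, function(s) strsplit(s, "")[[1L]]))
}

.srcChrom <- function(chrom) if (nzchar(chrom)) chrom else "chr"

# 0-based reference position per alignment column (NA at reference gaps)
.refCoords <- function(block, reference) {
  row <- strsplit(block$seq[[reference]], "")[[1L]]
  if (block$strand[[reference]] != "+")
    stop("reference rows must be on the + strand")
  pos <- rep(NA_integer_, length(row))
  ng <- row != "-"
  pos[ng] <- block$start[[reference]] + seq_len(sum(ng)) - 1L
  pos
}

# 0-based source position per column for one species row (NA at gaps),
# always on + strand coordinates
.speciesCoords <- function(block, sp) {
  row <- strsplit(block$seq[[sp]], "")[[1L]]
  pos <- rep(NA_integer_, length(row))
  ng <- row != "-"
  p <- block$start[[sp]] + seq_len(sum(ng)) - 1L
  if (block$strand[[sp]] == "-")
    p <- block$srcSize[[sp]] - 1L - p
  pos[ng] <- p
  pos
}

#' Extract per-element alignment slices
#'
#' Collects, for each reference interval, the alignment columns whose
#' reference position falls inside it (concatenated across blocks, in
#' reference order). The result is the per-element alignment used by the
#' acceleration test.
#'
#' @param maf A [MafAlignment-class].
#' @param gr `GRanges` of reference intervals (1-based, as `GRanges`).
#' @return Named list (by `mcols(gr)$id` when present) of character
#'   matrices; elements covered by no block yield a 0-column matrix.
#' @export
sliceAlignment <- function(maf, gr) {
  ids <- S4Vectors::mcols(gr)$id
  if (is.null(ids)) ids <- as.character(seq_along(gr))
  mats <- lapply(maf@blocks, blockMatrix)
  refpos <- lapply(maf@blocks, .refCoords, reference = maf@reference)
  refchr <- vapply(maf@blocks, function(b)
    .srcChrom(b$src[[maf@reference]]), "")
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    lo <- start(gr)[i] - 1L; hi <- end(gr)[i]  # 0-based half-open
    chr <- as.character(seqnames(gr))[i]
    pieces <- list()
    for (j in seq_along(mats)) {
      if (refchr[j] != chr) next
      keep <- which(!is.na(refpos[[j]]) & refpos[[j]] >= lo &
                      refpos[[j]] < hi)
      if (length(keep)) pieces[[length(pieces) + 1L]] <-
          mats[[j]][, keep, drop = FALSE]
    }
    out[[i]] <- if (length(pieces)) do.call(cbind, pieces) else
      matrix(character(0), nrow = 0, ncol = 0)
  }
  names(out) <- ids
  out
}

#' Project reference intervals onto subject species
#'
#' Maps each reference interval through the alignment blocks to every other
#' species: the projection is the union (per species) of the source
#' positions aligned to the interval's reference columns. Gaps shrink the
#' projection; a species absent from all covering blocks is unaligned
#' (empty projection); split alignments yield two or more intervals, which
#' the catalog filter flags as redundant.
#'
#' @inheritParams sliceAlignment
#' @param species Species to project onto (default: all non-reference
#'   species in the alignment).
#' @return Named list (per species) of `GRangesList` parallel to `gr`.
#' @export
projectToSpecies <- function(maf, gr, species = NULL) {
  allsp <- setdiff(mafSpecies(maf), maf@reference)
  if (is.null(species)) species <- allsp
  refpos <- lapply(maf@blocks, .refCoords, reference = maf@reference)
  refchr <- vapply(maf@blocks, function(b)
    .srcChrom(b$src[[maf@reference]]), "")
  sppos <- lapply(maf@blocks, function(b) {
    sapply(intersect(species, names(b$seq)), function(sp)
      .speciesCoords(b, sp), simplify = FALSE)
  })
  out <- sapply(species, function(sp) {
    grl <- lapply(seq_along(gr), function(i) {
      lo <- start(gr)[i] - 1L; hi <- end(gr)[i]
      chr <- as.character(seqnames(gr))[i]
      hits <- list()
      for (j in seq_along(maf@blocks)) {
        if (refchr[j] != chr || is.null(sppos[[j]][[sp]])) next
        inRange <- which(!is.na(refpos[[j]]) & refpos[[j]] >= lo &
                           refpos[[j]] < hi)
        if (!length(inRange)) next
        # include insertion columns (reference gaps) inside the window so
        # species insertions lengthen the projection
        keep <- min(inRange):max(inRange)
        p <- sppos[[j]][[sp]][keep]
        p <- p[!is.na(p)]
        if (length(p)) hits[[length(hits) + 1L]] <- GRanges(
          .srcChrom(maf@blocks[[j]]$src[[sp]]),
          IRanges(p + 1L, p + 1L))
      }
      if (!length(hits)) return(GRanges())
      reduce(sort(do.call(c, hits)))
    })
    GRangesList(grl)
  }, simplify = FALSE)
  out
}
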