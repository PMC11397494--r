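#' The packaged hand-checkable fixture bundle
#'
#' Returns the paths of the tiny deterministic fixture shipped with the
#' package (alignment, annotation, candidate segments, haplotype VCF,
#' diversity elements, precomputed bias calls, ortholog map, neighbor set)
#' together with the hand-computed expected outputs for each stage, and
#' builds the fixture's acceleration bundle: six 80-column element
#' alignments simulated from a fixed internal seed, one of which is planted
#' with strong acceleration (`lambda = 8`) on the three hermaphrodite
#' target branches. Every expected value in `expected/` was computed by
#' hand from the fixture's construction (see the fixture README); the
#' bundle underpins the end-to-end regression tests.
#'
#' Note: building the acceleration bundle sets the RNG seed to a fixed
#' internal value, so the bundle is identical on every call.
#'
#' @return List with `dir`, `paths` (named input file paths), `expected`
#'   (named expected-output file paths) and `accel`
#'   (`list(slices, planted, tree, model, targets)`).
#' @export
makeFixture <- function() {
  dir <- system.file("extdata", "fixture", package = "CNEaccel")
  if (!nzchar(dir)) stop("fixture directory not found; is the package installed?")
  p <- function(...) file.path(dir, ...)
  set.seed(424242L)
  tree <- caenoTree()
  model <- hky85(c(0.32, 0.18, 0.18, 0.32), kappa = 2)
  targets <- hermaphroditeSpecies()
  slices <- c(
    list(acc001 = simulateElementAlignment(tree, model, 80L, rho = 0.3,
                                           lambda = 8, targets = targets)),
    lapply(stats::setNames(1:5, sprintf("bg%03d", 1:5)), function(i)
      simulateElementAlignment(tree, model, 80L, rho = 0.3))
  )
  list(
    dir = dir,
    paths = list(
      segments = p("segments.bed"),
      gff = p("annotation.gff3"),
      maf = p("alignment.maf"),
      vcf = p("panel.vcf"),
      piElements = p("pi_elements.bed"),
      callsA = p("biascalls_speciesA.tsv"),
      callsB = p("biascalls_speciesB.tsv"),
      orthologs = p("orthologs.tsv"),
      neighbors = p("neighbor_genes.txt")
    ),
    expected = list(
      catalog = p("expected", "catalog.tsv"),
      nearest = p("expected", "nearest.tsv"),
      pi = p("expected", "pi.tsv"),
      transition = p("expected", "transition.tsv")
    ),
    accel = list(slices = slices, planted = "acc001", tree = tree,
                 model = model, targets = targets)
  )
}

#' Read a BED file of candidate segments or labelled elements
#'
#' Minimal BED reader (columns: chrom, start, end, optional name, optional
#' label) returning 1-based `GRanges`; the name column is stored as
#' `class` when `nameAs = "class"` or `id` otherwise, and a 5th column, if
#' present, is stored as the element `class` label.
#'
#' @param path BED file path.
#' @param nameAs How to store the 4th column (`"id"` or `"class"`).
#' @return `GRanges`.
#' @export
readBed <- function(path, nameAs = c("id", "class")) {
  nameAs <- match.arg(nameAs)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GRanges(df[[1L]], IRanges(df[[2L]] + 1L, df[[3L]]))
  if (ncol(df) >= 4L) mcols(gr)[[nameAs]] <- df[[4L]]
  if (ncol(df) >= 5L && nameAs == "id") mcols(gr)$class <- df[[5L]]
  gr
}

#' Read precomputed sex-bias calls
#'
#' Reads a two-column TSV (`gene`, `class`) of externally computed bias
#' calls, the bypass input for the differential-expression stand-in.
#'
#' @param path TSV path.
#' @return Named factor with levels `XX-biased`, `XO-biased`, `Non`.
#' @export
readBiasCalls <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- factor(df$class, levels = c("XX-biased", "XO-biased", "Non"))
  if (anyNA(out)) stop("unknown bias class in ", path)
  names(out) <- df$gene
  out
}
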