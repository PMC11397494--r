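#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median ratio of each
#' sample's counts to the per-gene geometric mean, using only genes nonzero
#' in every sample. When no gene is nonzero in all samples the function
#' falls back to upper-quartile factors scaled to geometric mean 1
#' (logged via `message`).
#'
#' @param counts Integer matrix, genes x samples.
#' @return Positive numeric vector of size factors, one per sample.
#' @export
medianOfRatios <- function(counts) {
  if (any(colSums(counts) == 0))
    stop("all-zero sample(s) cannot be normalised")
  allNonzero <- rowSums(counts == 0) == 0L
  if (!any(allNonzero)) {
    message("no gene nonzero in all samples; using upper-quartile factors")
    uq <- apply(counts, 2L, function(x) stats::quantile(x[x > 0], 0.75))
    return(uq / exp(mean(log(uq))))
  }
  logGeo <- rowMeans(log(counts[allNonzero, , drop = FALSE]))
  apply(counts[allNonzero, , drop = FALSE], 2L, function(x)
    exp(stats::median(log(x) - logGeo)))
}

# Conditional negative-binomial double-tail p-value for the group sums
# yA, yB (replicate counts nA, nB, common dispersion phi): the probability,
# conditional on the total, of all splits at most as probable as the
# observed one.
.nbExactP <- function(yA, yB, nA, nB, phi) {
  t <- yA + yB
  if (t == 0L) return(1)
  muT <- t / (nA + nB)
  y <- 0:t
  lp <- stats::dnbinom(y, size = nA / phi, mu = nA * muT, log = TRUE) +
    stats::dnbinom(t - y, size = nB / phi, mu = nB * muT, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[yA + 1L] * (1 + 1e-8)]))
}

#' Negative-binomial exact-style differential expression test
#'
#' A deliberately simple two-group differential-expression caller:
#' median-of-ratios normalisation, per-gene method-of-moments dispersion
#' (floored), and a conditional negative-binomial double-tail test on the
#' rounded normalised group sums, with Benjamini-Hochberg correction across
#' genes. The log2 fold change is `log2((meanB + 0.5) / (meanA + 0.5))` on
#' normalised counts, so swapping the groups negates it exactly. Genes zero
#' in all samples get `p = 1` and are flagged.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groupA,groupB Disjoint sample name (or index) vectors, each with
#'   at least two replicates.
#' @param dispersionFloor Lower bound for the per-gene dispersion.
#' @return `DataFrame`: `gene`, `baseMean`, `log2FC` (positive = higher in
#'   `groupB`), `dispersion`, `p`, `q`, `allZero`.
#' @export
deTest <- function(counts, groupA, groupB, dispersionFloor = 0.01) {
  a <- counts[, groupA, drop = FALSE]
  b <- counts[, groupB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least two replicates")
  if (length(intersect(colnames(a), colnames(b))))
    stop("groups must be disjoint")
  sub <- cbind(a, b)
  sf <- medianOfRatios(sub)
  pseudo <- sweep(sub, 2L, sf, "/")
  nA <- ncol(a); nB <- ncol(b)
  pa <- pseudo[, seq_len(nA), drop = FALSE]
  pb <- pseudo[, nA + seq_len(nB), drop = FALSE]
  meanA <- rowMeans(pa); meanB <- rowMeans(pb)

  # method-of-moments dispersion pooled over the two groups, then shrunk
  # toward the common (across-gene) value: raw per-gene estimates from a
  # handful of replicates are far too noisy and make the test
  # anti-conservative, so genewise values get prior weight as in
  # moderated-dispersion DE callers
  phiOf <- function(m, v) (v - m) / m^2
  phiA <- phiOf(meanA, apply(pa, 1L, stats::var))
  phiB <- phiOf(meanB, apply(pb, 1L, stats::var))
  wA <- nA - 1L; wB <- nB - 1L
  phiRaw <- (ifelse(is.finite(phiA), phiA, 0) * wA +
               ifelse(is.finite(phiB), phiB, 0) * wB) / (wA + wB)
  expressed <- meanA + meanB > 0
  phiCommon <- max(mean(phiRaw[expressed]), dispersionFloor)
  priorDf <- 20
  df <- wA + wB
  phi <- pmax((df * phiRaw + priorDf * phiCommon) / (df + priorDf),
              dispersionFloor)

  yA <- round(rowSums(pa)); yB <- round(rowSums(pb))
  allZero <- meanA + meanB == 0
  p <- rep(1, nrow(sub))
  idx <- which(!allZero)
  p[idx] <- vapply(idx, function(g)
    .nbExactP(yA[g], yB[g], nA, nB, phi[g]), 0)
  DataFrame(
    gene = rownames(counts),
    baseMean = (meanA + meanB) / 2,
    log2FC = log2((meanB + 0.5) / (meanA + 0.5)),
    dispersion = phi,
    p = p,
    q = stats::p.adjust(p, method = "BH"),
    allZero = allZero
  )
}

#' Classify genes into sex-bias classes
#'
#' Genes with `q < qThreshold` are labelled toward the sex with the higher
#' normalised mean (`XX-biased` when expression is higher in the XX group,
#' `XO-biased` when higher in the XO group); all other genes are `Non`.
#' The convention assumes [deTest()] was called with the XX samples as
#' `groupA` and the XO samples as `groupB`.
#'
#' @param de Output of [deTest()].
#' @param qThreshold FDR threshold (default 0.01).
#' @return Named factor (levels `XX-biased`, `XO-biased`, `Non`) per gene.
#' @export
classifySexBias <- function(de, qThreshold = 0.01) {
  cls <- ifelse(de$q < qThreshold & de$log2FC < 0, "XX-biased",
         ifelse(de$q < qThreshold & de$log2FC > 0, "XO-biased", "Non"))
  out <- factor(cls, levels = c("XX-biased", "XO-biased", "Non"))
  names(out) <- de$gene
  out
}

#' Sex-bias class proportions of CNE-neighbor genes
#'
#' For each comparison, contrasts the class distribution (XX-biased /
#' XO-biased / Non) of the accelerated-CNE-neighbor genes against all other
#' genes: a 2 x 3 table tested with Fisher's exact test when the total is
#' at most `exactMax` and with a chi-squared test above that, BH-corrected
#' across comparisons.
#'
#' @param callsList Named list (per comparison) of class factors from
#'   [classifySexBias()].
#' @param neighbors Character vector of neighbor gene ids (subset of the
#'   gene universe).
#' @param exactMax Largest table total for which the exact test is used.
#' @return List with `proportions` (per comparison, per bar) and `tests`
#'   (`DataFrame` of comparison, p, q, method).
#' @export
neighborBiasProportions <- function(callsList, neighbors, exactMax = 400) {
  if (!length(neighbors)) {
    message("empty neighbor set; no output")
    return(NULL)
  }
  tests <- lapply(names(callsList), function(cmp) {
    calls <- callsList[[cmp]]
    bad <- setdiff(neighbors, names(calls))
    if (length(bad))
      stop("neighbor gene(s) absent from universe: ",
           paste(utils::head(bad, 3), collapse = ", "))
    isN <- names(calls) %in% neighbors
    tab <- table(ifelse(isN, "neighbor", "other"), calls)
    method <- if (sum(tab) <= exactMax) "fisher" else "chisq"
    p <- if (method == "fisher") stats::fisher.test(tab)$p.value
    else suppressWarnings(stats::chisq.test(tab)$p.value)
    prop <- prop.table(tab, margin = 1L)
    list(cmp = cmp, p = p, method = method, prop = prop)
  })
  DF <- DataFrame(
    comparison = vapply(tests, `[[`, "", "cmp"),
    p = vapply(tests, `[[`, 0, "p"),
    method = vapply(tests, `[[`, "", "method")
  )
  DF$q <- stats::p.adjust(DF$p, method = "BH")
  list(proportions = stats::setNames(lapply(tests, `[[`, "prop"),
                                     DF$comparison),
       tests = DF)
}

#' Cross-species sex-bias transition table
#'
#' Places every one-to-one ortholog in a 3 x 3 cell by its sex-bias class
#' in species A and species B, then tests, per cell, whether
#' accelerated-CNE-neighbor genes are over- or under-represented in that
#' cell (2 x 2 Fisher's exact test, in-cell vs not x neighbor vs not), with
#' BH correction across the nine cells. The odds ratio is the sample odds
#' ratio, with 0.5 added to every cell when any cell is zero (the p-value
#' comes from the uncorrected exact test). A one-sided discordance
#' enrichment test is also reported: orthologs whose class differs between
#' the species versus neighbor status.
#'
#' @param callsA,callsB Named class factors (gene -> class) for the two
#'   species.
#' @param orthologs `data.frame` with columns `geneA`, `geneB` (one-to-one
#'   map).
#' @param neighbors Character vector of species-A neighbor gene ids.
#' @param alternative Alternative for the per-cell tests (default
#'   two-sided).
#' @return List with `cells` (`DataFrame` of classA, classB, n, nNeighbor,
#'   oddsRatio, p, q), `discordance` (`list(p, table)`), `nUsed` and
#'   `nExcluded`.
#' @export
transitionAssociation <- function(callsA, callsB, orthologs, neighbors,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  clsA <- callsA[orthologs$geneA]
  clsB <- callsB[orthologs$geneB]
  ok <- !is.na(clsA) & !is.na(clsB)
  nExcluded <- sum(!ok)
  if (nExcluded)
    message(nExcluded, " ortholog(s) without calls in both species excluded")
  clsA <- clsA[ok]; clsB <- clsB[ok]
  isN <- orthologs$geneA[ok] %in% neighbors
  lev <- c("XX-biased", "XO-biased", "Non")
  total <- sum(ok); totN <- sum(isN)
  rows <- list()
  for (la in lev) for (lb in lev) {
    inCell <- clsA == la & clsB == lb
    a <- sum(inCell & isN); b <- sum(inCell & !isN)
    c_ <- sum(!inCell & isN); d <- sum(!inCell & !isN)
    p <- if (total == 0L || sum(inCell) %in% c(0L, total) ||
             totN %in% c(0L, total)) 1
    else fisherP(a, b, c_, d, alternative)
    orr <- if (any(c(a, b, c_, d) == 0L))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    rows[[paste(la, lb)]] <- DataFrame(
      classA = la, classB = lb, n = sum(inCell), nNeighbor = a,
      oddsRatio = orr, p = p)
  }
  cells <- do.call(rbind, rows)
  cells$q <- stats::p.adjust(cells$p, method = "BH")
  disc <- clsA != clsB
  discP <- if (total == 0L || !any(disc) || all(disc) ||
               totN %in% c(0L, total)) 1
  else fisherP(sum(disc & isN), sum(disc & !isN),
               sum(!disc & isN), sum(!disc & !isN), "greater")
  list(cells = cells,
       discordance = list(p = discP,
                          table = table(discordant = disc,
                                        neighbor = isN)),
       nUsed = total, nExcluded = nExcluded)
}
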