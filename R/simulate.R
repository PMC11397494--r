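#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults that
#' emulate the statistical structure the analysis assumes: an 11-taxon tree
#' with the three hermaphrodite terminal branches as acceleration targets,
#' conserved elements at branch scale `rho = 0.3` (the HMM's conserved
#' scale), accelerated elements at `lambda = 5` on the target branches,
#' AT-rich base composition, a wild-isolate-style haplotype panel with a
#' five-fold diversity reduction inside CNEs, and negative-binomial counts
#' with four replicates per group and two-fold planted sex bias.
#'
#' @param seed Integer seed; every generator derives its RNG stream from it.
#' @param tree Species tree (`ape::phylo`).
#' @param reference Reference/outgroup species anchoring the alignment.
#' @param chromName Simulated chromosome name.
#' @param refLength Reference chromosome length (bp).
#' @param nCne Number of planted conserved noncoding elements.
#' @param cneLengthRange Min/max planted element length (bp).
#' @param accelFraction Fraction of planted elements that are additionally
#'   accelerated on the target branches.
#' @param rho Conserved-state branch scale in (0, 1].
#' @param lambda Acceleration scale (>= 1) on target branches.
#' @param targets Target branch names (child-node labels).
#' @param cdsFraction Approximate fraction of the chromosome covered by
#'   coding sequence.
#' @param gapFraction Fraction of non-reference cells masked as gaps.
#' @param model Substitution model ([NucModel-class]).
#' @param blockSize Columns per MAF block on output.
#' @param nHaplotypes Haplotypes in the population panel.
#' @param thetaNeutral Per-site scaled mutation rate outside CNEs.
#' @param cneThetaReduction Fold reduction of theta inside CNEs.
#' @param nGenes One-to-one ortholog (gene) count for the expression
#'   simulation.
#' @param nbMean Median negative-binomial mean expression.
#' @param nbDispersion Negative-binomial dispersion.
#' @param biasFractions Named fractions of XX- and XO-biased genes.
#' @param foldChange Planted expression fold change of biased genes.
#' @param replicates Replicates per sex/stage group.
#' @param neighborFraction Fraction of genes flagged as accelerated-CNE
#'   neighbors.
#' @param transitionOR Planted neighbor odds ratio in the enriched
#'   transition cell.
#' @param enrichedCell Length-2 character vector `(class in A, class in B)`
#'   naming the enriched transition cell.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(seed = 1,
                      tree = caenoTree(),
                      reference = "C_niphades",
                      chromName = "chrI",
                      refLength = 20000L,
                      nCne = 40L,
                      cneLengthRange = c(20L, 120L),
                      accelFraction = 0.1,
                      rho = 0.3,
                      lambda = 5,
                      targets = hermaphroditeSpecies(),
                      cdsFraction = 0.25,
                      gapFraction = 0,
                      model = hky85(c(0.32, 0.18, 0.18, 0.32), kappa = 2),
                      blockSize = 5000L,
                      nHaplotypes = 30L,
                      thetaNeutral = 0.005,
                      cneThetaReduction = 5,
                      nGenes = 10000L,
                      nbMean = 100,
                      nbDispersion = 0.1,
                      biasFractions = c(XX = 0.15, XO = 0.15),
                      foldChange = 2,
                      replicates = 4L,
                      neighborFraction = 0.05,
                      transitionOR = 3,
                      enrichedCell = c("Non", "XX-biased")) {
  cfg <- as.list(environment())
  stopifnot(cfg$rho > 0, cfg$rho <= 1, cfg$lambda >= 1,
            cfg$thetaNeutral > 0, cfg$cneThetaReduction >= 1,
            cfg$accelFraction >= 0, cfg$accelFraction <= 1)
  class(cfg) <- "simConfig"
  cfg
}

# simulate one child sequence from a parent along a branch, site categories
# selecting among precomputed transition matrices
.evolveSeq <- function(parent, Plist, cat) {
  child <- character(length(parent))
  for (k in seq_along(Plist)) {
    P <- Plist[[k]]
    for (b in 1:4) {
      idx <- which(parent == .BASES[b] & cat == k)
      if (length(idx))
        child[idx] <- sample(.BASES, length(idx), replace = TRUE,
                             prob = P[b, ])
    }
  }
  child
}

#' Simulate one element alignment
#'
#' Evolves `nCols` independent columns down the tree under the HKY model,
#' with all branches scaled by `rho` and target branches additionally
#' scaled by `lambda`. Uses the current RNG state (call `set.seed()`
#' first for reproducibility).
#'
#' @param tree,model Phylogeny and substitution model.
#' @param nCols Number of columns.
#' @param rho Branch scale applied to every branch.
#' @param lambda Extra scale on the target branches.
#' @param targets Target branch names (child-node labels).
#' @return Character matrix (species x columns).
#' @export
simulateElementAlignment <- function(tree, model, nCols, rho = 1,
                                     lambda = 1, targets = character(0)) {
  machine <- .pruneMachine(tree)
  cl <- ape::reorder.phylo(tree, "cladewise")
  seqs <- vector("list", machine$ntip + machine$nnode)
  seqs[[machine$ntip + 1L]] <- sample(.BASES, nCols, replace = TRUE,
                                      prob = model@freqs)
  ntip <- machine$ntip
  labOf <- function(ch) if (ch <= ntip) cl$tip.label[ch] else
    paste0("node", ch)
  cat1 <- rep(1L, nCols)
  for (e in seq_len(nrow(cl$edge))) {
    par <- cl$edge[e, 1L]; ch <- cl$edge[e, 2L]
    sc <- rho * if (labOf(ch) %in% targets) lambda else 1
    P <- transitionMatrix(model, cl$edge.length[e] * sc)
    seqs[[ch]] <- .evolveSeq(seqs[[par]], list(P), cat1)
  }
  do.call(rbind, stats::setNames(seqs[seq_len(ntip)], cl$tip.label))
}

#' Simulate a reference-anchored alignment with planted elements
#'
#' Lays out non-overlapping coding (CDS) intervals and conserved noncoding
#' elements on a simulated reference chromosome, evolves the sequences down
#' the tree (neutral background at scale 1; CDS and conserved elements at
#' branch scale `rho`; accelerated elements additionally at `lambda` on the
#' target branches), and returns the alignment together with the ground
#' truth. When `dir` is given, writes `alignment.maf`, `reference.fa`,
#' `annotation.gff3`, `truth_conserved.bed`, `truth_accelerated.bed` and a
#' `manifest.json` recording the seed. Deterministic given the seed.
#'
#' @param config A [simConfig()].
#' @param dir Optional output directory.
#' @return List with `maf` ([MafAlignment-class]), `truth` (`GRanges` of
#'   planted noncoding elements, with `accelerated`, `lambda` columns),
#'   `cds` and `genes` (`GRanges`), `refSeq` (character vector) and `paths`.
#' @export
simulateAlignment <- function(config, dir = NULL) {
  set.seed(config$seed)
  L <- as.integer(config$refLength)
  nCne <- as.integer(config$nCne)
  cneLens <- sample(config$cneLengthRange[1L]:config$cneLengthRange[2L],
                    nCne, replace = TRUE)
  cdsLens <- integer(0)
  targetCds <- config$cdsFraction * L
  while (sum(cdsLens) < targetCds)
    cdsLens <- c(cdsLens, sample(150:400, 1L))
  feat <- c(rep("cne", nCne), rep("cds", length(cdsLens)))
  lens <- c(cneLens, cdsLens)
  ord <- sample(length(feat))
  feat <- feat[ord]; lens <- lens[ord]
  slack <- L - sum(lens)
  if (slack < length(feat) + 1L)
    stop("element layout exceeds chromosome length; reduce nCne or ",
         "cdsFraction")
  gaps <- as.vector(stats::rmultinom(1L, slack - (length(feat) + 1L),
                                     rep(1, length(feat) + 1L))) + 1L
  starts0 <- cumsum(gaps[seq_along(lens)]) +
    cumsum(c(0L, lens[-length(lens)]))  # 0-based
  isCne <- feat == "cne"
  cne <- GRanges(rep(config$chromName, sum(isCne)),
                 IRanges(starts0[isCne] + 1L, width = lens[isCne]))
  cds <- GRanges(rep(config$chromName, sum(!isCne)),
                 IRanges(starts0[!isCne] + 1L, width = lens[!isCne]))
  nAccel <- round(config$accelFraction * nCne)
  accIdx <- if (nAccel > 0) sample(nCne, nAccel) else integer(0)
  mcols(cne)$accelerated <- seq_len(nCne) %in% accIdx
  mcols(cne)$lambda <- ifelse(mcols(cne)$accelerated, config$lambda, 1)

  # per-site category: 1 neutral, 2 conserved (rho), 3 accelerated
  cat <- rep(1L, L)
  for (i in seq_along(cds)) cat[start(cds)[i]:end(cds)[i]] <- 2L
  for (i in seq_along(cne))
    cat[start(cne)[i]:end(cne)[i]] <- if (mcols(cne)$accelerated[i]) 3L
      else 2L

  machine <- .pruneMachine(config$tree)
  cl <- ape::reorder.phylo(config$tree, "cladewise")
  ntip <- machine$ntip
  labOf <- function(ch) if (ch <= ntip) cl$tip.label[ch] else
    paste0("node", ch)
  seqs <- vector("list", ntip + machine$nnode)
  seqs[[ntip + 1L]] <- sample(.BASES, L, replace = TRUE,
                              prob = config$model@freqs)
  for (e in seq_len(nrow(cl$edge))) {
    par <- cl$edge[e, 1L]; ch <- cl$edge[e, 2L]
    onTarget <- labOf(ch) %in% config$targets
    t0 <- cl$edge.length[e]
    Plist <- list(
      transitionMatrix(config$model, t0),
      transitionMatrix(config$model, t0 * config$rho),
      transitionMatrix(config$model, t0 * config$rho *
                         if (onTarget) config$lambda else 1)
    )
    seqs[[ch]] <- .evolveSeq(seqs[[par]], Plist, cat)
  }
  aln <- do.call(rbind, stats::setNames(seqs[seq_len(ntip)], cl$tip.label))
  if (config$gapFraction > 0) {
    for (sp in setdiff(rownames(aln), config$reference)) {
      mask <- stats::runif(L) < config$gapFraction
      aln[sp, mask] <- "-"
    }
  }

  blocks <- list()
  for (s in seq(1L, L, by = config$blockSize)) {
    e <- min(L, s + config$blockSize - 1L)
    sp <- rownames(aln)
    blocks[[length(blocks) + 1L]] <- list(
      src = stats::setNames(rep(config$chromName, length(sp)), sp),
      start = stats::setNames(rep(s - 1L, length(sp)), sp),
      size = stats::setNames(rep(e - s + 1L, length(sp)), sp),
      strand = stats::setNames(rep("+", length(sp)), sp),
      srcSize = stats::setNames(rep(L, length(sp)), sp),
      seq = stats::setNames(
        apply(aln[, s:e, drop = FALSE], 1L, paste, collapse = ""), sp)
    )
  }
  maf <- new("MafAlignment", blocks = blocks, reference = config$reference)

  genes <- GRanges(rep(config$chromName, length(cds)),
                   IRanges(pmax(1L, start(cds) - 20L),
                           pmin(L, end(cds) + 20L)))
  mcols(genes)$gene_id <- sprintf("g%04d", seq_along(genes))
  mcols(cds)$gene_id <- mcols(genes)$gene_id

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      maf = file.path(dir, "alignment.maf"),
      fasta = file.path(dir, "reference.fa"),
      gff = file.path(dir, "annotation.gff3"),
      conservedBed = file.path(dir, "truth_conserved.bed"),
      acceleratedBed = file.path(dir, "truth_accelerated.bed"),
      manifest = file.path(dir, "manifest.json")
    )
    writeMaf(maf, paths$maf)
    refSet <- Biostrings::DNAStringSet(
      stats::setNames(paste(aln[config$reference, ], collapse = ""),
                      config$chromName))
    Biostrings::writeXStringSet(refSet, paths$fasta)
    gff <- c(genes, cds)
    mcols(gff)$type <- rep(c("gene", "CDS"), c(length(genes), length(cds)))
    mcols(gff)$ID <- c(mcols(genes)$gene_id,
                       paste0(mcols(cds)$gene_id, ".cds"))
    mcols(gff)$Parent <- c(rep(NA_character_, length(genes)),
                           mcols(cds)$gene_id)
    mcols(gff)$phase <- rep(c(NA_integer_, 0L),
                            c(length(genes), length(cds)))
    rtracklayer::export.gff3(gff, paths$gff)
    .writeBed(cne, paths$conservedBed,
              names = sprintf("cne%03d", seq_along(cne)))
    acc <- cne[mcols(cne)$accelerated]
    .writeBed(acc, paths$acceleratedBed,
              names = sprintf("lambda=%g;targets=%s", mcols(acc)$lambda,
                              paste(config$targets, collapse = ",")))
    jsonlite::write_json(
      list(seed = config$seed, generator = "simulateAlignment",
           refLength = L, nCne = nCne, rho = config$rho,
           lambda = config$lambda, targets = config$targets),
      paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(maf = maf, truth = cne, cds = cds, genes = genes,
       refSeq = aln[config$reference, ], paths = paths)
}

# minimal BED6 writer (0-based half-open)
.writeBed <- function(gr, path, names = NULL, scores = 0) {
  if (is.null(names)) names <- as.character(seq_along(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = names, score = scores, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a population haplotype panel (VCF)
#'
#' Places segregating sites site-independently with probability
#' `theta * a_n` per base (`a_n` the Watterson harmonic factor for the
#' panel size), reduced `cneThetaReduction`-fold inside the planted CNEs.
#' Derived-allele counts follow the neutral frequency prior (probability
#' proportional to `1/i`), and carriers are drawn uniformly. Writes a
#' haploid plain-text VCF when `dir` is given. Deterministic given the
#' seed.
#'
#' @param config A [simConfig()].
#' @param refSeq Character vector: the reference chromosome sequence.
#' @param truth `GRanges` of planted CNEs (diversity is reduced inside).
#' @param dir Optional output directory.
#' @return List with `panel` ([HaplotypePanel-class]) and `paths`.
#' @export
simulatePopulation <- function(config, refSeq, truth, dir = NULL) {
  set.seed(config$seed + 1000003L)
  L <- length(refSeq)
  n <- as.integer(config$nHaplotypes)
  an <- sum(1 / seq_len(n - 1L))
  pSeg <- rep(min(1, config$thetaNeutral * an), L)
  if (length(truth)) {
    inCne <- rep(FALSE, L)
    for (i in seq_along(truth))
      inCne[start(truth)[i]:end(truth)[i]] <- TRUE
    pSeg[inCne] <- pSeg[inCne] / config$cneThetaReduction
  }
  segPos <- which(stats::runif(L) < pSeg)
  nSite <- length(segPos)
  geno <- matrix(0L, nSite, n)
  derived <- sample(seq_len(n - 1L), nSite, replace = TRUE,
                    prob = 1 / seq_len(n - 1L))
  for (s in seq_len(nSite))
    geno[s, sample(n, derived[s])] <- 1L
  ref <- toupper(refSeq[segPos])
  alt <- vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), "")
  samples <- sprintf("s%02d", seq_len(n))
  colnames(geno) <- samples
  panel <- new("HaplotypePanel",
               chrom = rep(config$chromName, nSite),
               pos = as.integer(segPos),
               ref = ref, alt = unname(alt), geno = geno,
               samples = samples)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "panel.vcf"),
                  manifest = file.path(dir, "panel_manifest.json"))
    .writeVcf(panel, paths$vcf, contigLength = L)
    jsonlite::write_json(
      list(seed = config$seed, generator = "simulatePopulation",
           nHaplotypes = n, thetaNeutral = config$thetaNeutral,
           cneThetaReduction = config$cneThetaReduction),
      paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(panel = panel, paths = paths)
}

# plain-text haploid VCF writer for simulated panels
.writeVcf <- function(panel, path, contigLength = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigLength))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       unique(panel@chrom)[1L], contigLength), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(panel@geno)),
                   collapse = "\t"), con)
  if (nrow(panel@geno)) {
    gt <- panel@geno
    gt[is.na(gt)] <- "."
    lines <- paste(panel@chrom, panel@pos, ".", panel@ref, panel@alt, ".",
                   "PASS", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Simulate cross-species expression count matrices
#'
#' Generates one-to-one orthologs with planted sex-bias classes per
#' species, a neighbor flag enriched at the configured odds ratio in the
#' configured transition cell, and negative-binomial counts (four
#' replicates per sex and stage by default; two-fold planted bias). Writes
#' counts, metadata, the ortholog map, the neighbor list and the truth
#' classes as TSV when `dir` is given. Deterministic given the seed.
#'
#' @param config A [simConfig()].
#' @param dir Optional output directory.
#' @return List with `counts` (named list per species), `metadata`,
#'   `orthologs`, `neighbors`, `truth` (`data.frame` of planted classes)
#'   and `paths`.
#' @export
simulateExpression <- function(config, dir = NULL) {
  set.seed(config$seed + 2000003L)
  G <- as.integer(config$nGenes)
  lev <- c("XX-biased", "XO-biased", "Non")
  pXX <- config$biasFractions[["XX"]]
  pXO <- config$biasFractions[["XO"]]
  pCls <- c(pXX, pXO, 1 - pXX - pXO)
  clsA <- sample(lev, G, replace = TRUE, prob = pCls)
  clsB <- sample(lev, G, replace = TRUE, prob = pCls)

  inCell <- clsA == config$enrichedCell[1L] & clsB == config$enrichedCell[2L]
  pCell <- mean(inCell)
  OR <- config$transitionOR
  pN <- config$neighborFraction
  f <- function(q0) {
    q1 <- OR * q0 / (1 - q0 + OR * q0)
    pCell * q1 + (1 - pCell) * q0 - pN
  }
  if (pCell == 0)
    stop("enriched cell (", paste(config$enrichedCell, collapse = ", "),
         ") received no orthologs; planted odds ratio infeasible at ",
         "nGenes = ", G)
  if (pN >= 1 || f(1 - 1e-9) < 0)
    stop("infeasible neighborFraction; feasible bound < 1")
  q0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  q1 <- OR * q0 / (1 - q0 + OR * q0)
  neighbor <- stats::runif(G) < ifelse(inCell, q1, q0)

  mu <- stats::rlnorm(G, meanlog = log(config$nbMean), sdlog = 1)
  stages <- c("L4", "young_adult")
  reps <- config$replicates
  mkCounts <- function(cls) {
    cols <- list()
    meta <- list()
    for (st in stages) for (sex in c("XX", "XO")) {
      m <- mu
      up <- (cls == "XX-biased" & sex == "XX") |
        (cls == "XO-biased" & sex == "XO")
      m[up] <- m[up] * config$foldChange
      for (r in seq_len(reps)) {
        nm <- paste(st, sex, r, sep = "_")
        cols[[nm]] <- stats::rnbinom(G, size = 1 / config$nbDispersion,
                                     mu = m)
        meta[[nm]] <- data.frame(sample = nm, sex = sex, stage = st,
                                 replicate = r)
      }
    }
    list(counts = do.call(cbind, cols), meta = do.call(rbind, meta))
  }
  genesA <- sprintf("ceg%05d", seq_len(G))
  genesB <- sprintf("cig%05d", seq_len(G))
  A <- mkCounts(clsA); B <- mkCounts(clsB)
  rownames(A$counts) <- genesA
  rownames(B$counts) <- genesB
  metaA <- cbind(species = "speciesA", A$meta)
  metaB <- cbind(species = "speciesB", B$meta)
  orthologs <- data.frame(geneA = genesA, geneB = genesB)
  truth <- data.frame(geneA = genesA, geneB = genesB,
                      classA = clsA, classB = clsB, neighbor = neighbor)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      countsA = file.path(dir, "counts_speciesA.tsv"),
      countsB = file.path(dir, "counts_speciesB.tsv"),
      metadata = file.path(dir, "sample_metadata.tsv"),
      orthologs = file.path(dir, "orthologs.tsv"),
      neighbors = file.path(dir, "neighbor_genes.txt"),
      truth = file.path(dir, "truth_expression.tsv"),
      manifest = file.path(dir, "expression_manifest.json")
    )
    utils::write.table(A$counts, paths$countsA, sep = "\t", quote = FALSE)
    utils::write.table(B$counts, paths$countsB, sep = "\t", quote = FALSE)
    utils::write.table(rbind(metaA, metaB), paths$metadata, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(orthologs, paths$orthologs, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(genesA[neighbor], paths$neighbors)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, generator = "simulateExpression",
           nGenes = G, transitionOR = OR,
           enrichedCell = config$enrichedCell),
      paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(counts = list(speciesA = A$counts, speciesB = B$counts),
       metadata = rbind(metaA, metaB), orthologs = orthologs,
       neighbors = genesA[neighbor], truth = truth, paths = paths)
}
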