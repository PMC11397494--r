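# Independent brute-force oracles used by unit and acceptance tests.
# These deliberately avoid the package's pruning / HMM / estimator code
# paths: likelihoods are enumerated over internal states or state paths,
# Fisher tails over binomial coefficients, and pi over haplotype pairs.

# column likelihood by exhaustive enumeration over internal-node states
bruteColumnLoglik <- function(tree, model, column, scale = 1) {
  tt <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tt$tip.label)
  nn <- ntip + tt$Nnode
  bases <- c("A", "C", "G", "T")
  Ps <- lapply(seq_len(nrow(tt$edge)), function(e)
    transitionMatrix(model, tt$edge.length[e] * scale))
  leafStates <- lapply(column[tt$tip.label], function(s) {
    if (s %in% c("N", "-")) 1:4 else match(s, bases)
  })
  inodes <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(1:4), length(inodes)))
  leafGrid <- expand.grid(leafStates)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    for (h in seq_len(nrow(leafGrid))) {
      st <- integer(nn)
      st[inodes] <- as.integer(grid[g, ])
      st[seq_len(ntip)] <- as.integer(leafGrid[h, ])
      pr <- unname(model@freqs[st[ntip + 1L]])
      for (e in seq_len(nrow(tt$edge)))
        pr <- pr * Ps[[e]][st[tt$edge[e, 1L]], st[tt$edge[e, 2L]]]
      total <- total + pr
    }
  }
  log(total)
}

# random rooted tree with branch lengths, for property loops
randomTree <- function(ntips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(ntips, rooted = TRUE,
                   tip.label = paste0("t", seq_len(ntips)))
  tr$edge.length <- round(stats::runif(nrow(tr$edge), 0.02, 0.5), 3)
  tr
}

# HMM forward by enumeration over all 2^L state paths (1 = conserved)
bruteForwardLoglik <- function(em, mu, nu) {
  mu <- unname(mu); nu <- unname(nu)
  L <- ncol(em)
  g <- nu / (mu + nu)
  Tm <- matrix(c(1 - mu, nu, mu, 1 - nu), 2, 2)
  tot <- 0
  for (mask in 0:(2^L - 1)) {
    st <- as.integer(intToBits(mask))[seq_len(L)] + 1L
    pr <- c(g, 1 - g)[st[1L]] * exp(em[st[1L], 1L])
    if (L > 1L) for (i in 2:L)
      pr <- pr * Tm[st[i - 1L], st[i]] * exp(em[st[i], i])
    tot <- tot + pr
  }
  log(tot)
}

# best path score by the same enumeration
bruteViterbiScore <- function(em, mu, nu) {
  mu <- unname(mu); nu <- unname(nu)
  L <- ncol(em)
  g <- nu / (mu + nu)
  Tm <- matrix(c(1 - mu, nu, mu, 1 - nu), 2, 2)
  best <- -Inf
  for (mask in 0:(2^L - 1)) {
    st <- as.integer(intToBits(mask))[seq_len(L)] + 1L
    lp <- log(c(g, 1 - g)[st[1L]]) + em[st[1L], 1L]
    if (L > 1L) for (i in 2:L)
      lp <- lp + log(Tm[st[i - 1L], st[i]]) + em[st[i], i]
    if (lp > best) best <- lp
  }
  best
}

# one-sided (enrichment) Fisher tail from binomial coefficients only
bruteFisherGreater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  hi <- min(m, k)
  j <- a:hi
  sum(choose(m, j) * choose(n, k - j)) / choose(m + n, k)
}

# pi from mean pairwise differences among haplotypes, per element
brutePi <- function(panel, element) {
  lo <- GenomicRanges::start(element); hi <- GenomicRanges::end(element)
  chr <- as.character(GenomicRanges::seqnames(element))
  use <- which(panel@chrom == chr & panel@pos >= lo & panel@pos <= hi)
  total <- 0
  for (s in use) {
    gt <- panel@geno[s, ]
    gt <- gt[!is.na(gt)]
    ns <- length(gt)
    if (ns < 2) next
    diffs <- 0
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns)
      diffs <- diffs + (gt[i] != gt[j])
    total <- total + diffs / (ns * (ns - 1) / 2)
  }
  total / GenomicRanges::width(element)
}

# shared tree/model used across statistical tests
testTree <- caenoTree()
testModel <- hky85(c(0.32, 0.18, 0.18, 0.32), kappa = 2)
testTargets <- hermaphroditeSpecies()
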