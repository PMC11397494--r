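gr <- function(s, e, chrom = "chrI")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))

test_that("coding subtraction returns maximal noncoding sub-intervals", {
  # half overlap: [100,140) minus CDS [120,200) -> [100,120)
  out <- subtractCoding(gr(101, 140), gr(121, 200))
  expect_equal(GenomicRanges::start(out), 101)
  expect_equal(GenomicRanges::end(out), 120)

  # fully contained segment disappears
  expect_length(subtractCoding(gr(130, 150), gr(121, 200)), 0)

  # two internal CDS split a segment into three pieces
  out <- subtractCoding(gr(1, 100), c(gr(21, 30), gr(61, 70)))
  expect_equal(GenomicRanges::start(out), c(1, 31, 71))
  expect_equal(GenomicRanges::end(out), c(20, 60, 100))

  # adjacent segments are never merged
  out <- subtractCoding(c(gr(1, 10), gr(11, 20)), gr(500, 600))
  expect_length(out, 2)
  expect_equal(out$segment, 1:2)

  # chromosome without CDS annotation passes through with a warning
  expect_warning(
    out <- subtractCoding(gr(1, 50, "chrX"), gr(1, 10, "chrI")),
    "chrX")
  expect_equal(GenomicRanges::width(out), 50)

  # brute-force per-base membership on random cases
  set.seed(51)
  for (i in 1:20) {
    segs <- gr(s <- sample(500, 5), s + sample(10:80, 5, replace = TRUE))
    cds <- GenomicRanges::reduce(
      gr(cs <- sample(600, 6), cs + sample(5:50, 6, replace = TRUE)))
    out <- subtractCoding(segs, cds)
    inSeg <- unique(unlist(Map(seq, GenomicRanges::start(segs),
                               GenomicRanges::end(segs))))
    inCds <- unlist(Map(seq, GenomicRanges::start(cds),
                        GenomicRanges::end(cds)))
    inOut <- unlist(Map(seq, GenomicRanges::start(out),
                        GenomicRanges::end(out)))
    expect_setequal(inOut, setdiff(inSeg, inCds))
  }
})

test_that("minimum-length rule is strictly greater-than", {
  segs <- gr(rep(1, 6), c(5, 10, 11, 12, 50, 8))  # widths 5,10,11,12,50,8
  kept <- filterMinLength(segs)
  expect_equal(GenomicRanges::width(kept), c(11, 12, 50))
})

test_that("species filters apply the redundancy and 2x length rules", {
  fx <- makeFixture()
  maf <- readMaf(fx$paths$maf, reference = "C_niphades")
  gff <- rtracklayer::import(fx$paths$gff)
  catalog <- buildCneCatalog(readBed(fx$paths$segments),
                             gff[gff$type == "CDS"], maf)
  st <- cneStatus(catalog)
  # boundary: projection 45 > 2 x 20 dropped; exactly 2 x stays kept
  expect_equal(unname(st["C_inopinata", "CNE00001"]),
               "dropped_length_ratio")
  expect_equal(unname(st["C_briggsae", "CNE00003"]), "dropped_redundant")
  expect_equal(unname(st["C_briggsae", "CNE00006"]), "unaligned")
  expect_equal(sum(st == "kept"), 15)
  expect_setequal(keptCnes(catalog, "C_elegans"),
                  sprintf("CNE%05d", 1:6))
  # boundary of the strict 2x rule: 24 vs reference 12 is kept
  r <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 12), id = "a")
  fakeProj <- list(sp = GenomicRanges::GRangesList(list(gr(1, 24))))
  expect_true(sum(GenomicRanges::width(fakeProj$sp[[1]])) <= 2 * 12)
})

test_that("nearest gene assignment handles overlap, ties and distance signs", {
  genes <- c(gr(1, 50), gr(131, 200))
  genes$gene_id <- c("gLeft", "gRight")
  # [100,120) 0-based: nearest is the right gene at gap 10
  res <- nearestGene(gr(101, 120), genes)
  expect_equal(res$gene_id, "gRight")
  expect_equal(res$distance, 10)

  # containment gives distance 0
  res <- nearestGene(gr(140, 150), genes)
  expect_equal(res$gene_id, "gRight")
  expect_equal(res$distance, 0)

  # no gene on the chromosome
  expect_warning(res <- nearestGene(gr(1, 10, "chrZ"), genes), "without")
  expect_true(is.na(res$gene_id))

  # random placements match the exhaustive all-pairs oracle
  set.seed(52)
  genes <- gr(s <- sample(5000, 40), s + sample(50:200, 40, replace = TRUE))
  genes$gene_id <- sprintf("g%02d", seq_along(genes))
  qs <- sample(5000, 200)
  q <- gr(qs, qs + sample(10:60, 200, replace = TRUE))
  res <- nearestGene(q, genes)
  for (i in seq_len(200)) {
    gaps <- pmax(GenomicRanges::start(genes) - GenomicRanges::end(q)[i] - 1,
                 GenomicRanges::start(q)[i] - GenomicRanges::end(genes) - 1)
    gaps <- pmax(gaps, 0)
    expect_equal(abs(res$distance[i]), min(gaps))
  }
})

test_that("Fisher p-values and annotation enrichment match enumeration", {
  # [[3,1],[1,3]] one-sided: 17/70
  expect_equal(fisherP(3, 1, 1, 3, "greater"), 17 / 70, tolerance = 1e-12)
  # agreement with fisher.test on random tables, all alternatives
  set.seed(53)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(fisherP(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2], alt),
                   stats::fisher.test(tab, alternative = alt)$p.value,
                   tolerance = 1e-9)
    }
  }

  cnes <- gr(c(1, 101, 201, 301, 401, 501, 601, 701),
             c(50, 150, 250, 350, 450, 550, 650, 750))
  cnes$id <- sprintf("c%d", 1:8)
  ann <- list(enhancer = gr(c(10, 110, 210, 310), c(20, 120, 220, 320)),
              promoter = gr(720, 730))
  enr <- annotationEnrichment(sprintf("c%d", 1:4), cnes$id, cnes, ann)
  expect_equal(enr$accelOverlap[enr$feature == "enhancer"], 4)
  expect_equal(enr$otherOverlap[enr$feature == "enhancer"], 0)
  expect_equal(enr$p[enr$feature == "enhancer"],
               bruteFisherGreater(4, 0, 0, 4), tolerance = 1e-12)
  # accelerated set == universe: no contrast
  enrAll <- annotationEnrichment(cnes$id, cnes$id, cnes, ann)
  expect_true(all(enrAll$p == 1))
  expect_error(annotationEnrichment("zz", cnes$id, cnes, ann), "subset")

  # BH on a hand-computed vector
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})
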