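test_that("Poisson window p-value matches the brute-force tail sum", {
  ## independent oracle: explicit partial sum of the Poisson pmf
  bruteTail <- function(k, lambda) {
    kk <- k:max(k + 400, ceiling(lambda + 40 * sqrt(lambda)))
    sum(exp(-lambda + kk * log(lambda) - lfactorial(kk)))
  }
  expect_equal(poissonPeakPvalue(10, 2), bruteTail(10, 2), tolerance = 1e-13)
  set.seed(21)
  for (i in 1:50) {
    k <- sample(0:60, 1); lam <- runif(1, 0.1, 30)
    expect_equal(poissonPeakPvalue(k, lam), bruteTail(k, lam),
                 tolerance = 1e-12)
  }
  ## monotonicity: p strictly decreases in the count at fixed expectation
  p <- poissonPeakPvalue(0:50, 5)
  expect_true(all(diff(p) < 0))
})

test_that("proportional IP and control yield no significant windows", {
  anno <- toyAnnotation()
  ## deterministic: control anchors every 10 nt, IP the same places 10x
  ctrlOff <- seq(0, 499, by = 10)
  ipOff <- rep(ctrlOff, each = 10)
  ip <- readsFromTxOffsets(anno, "t1", ipOff, len = 30, sampleId = "ip")
  ctrl <- readsFromTxOffsets(anno, "t1", ctrlOff, len = 30, sampleId = "ctrl")
  pc <- callPeaks(ip, ctrl, anno, keepWindows = TRUE)
  expect_equal(length(peaks(pc)), 0L)
  w <- peakParams(pc)$windows
  expect_true(all(w$q > 0.05))
})

test_that("a spiked window produces one merged peak with an interior summit", {
  ## 10 kb intronless gene, uniform 0.1 reads/nt background plus a 50-nt
  ## window at 20x background
  df <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", utr5_len = 500, cds_len = 8000,
                   utr3_len = 1500, gene_type = "protein_coding")
  anno <- makeTranscriptAnnotation(
    df, GRangesList(t1 = GRanges("chr1", IRanges(1, 10000))))
  set.seed(77)
  bg <- sample.int(10000, rpois(1, 0.1 * 10000), replace = TRUE) - 1
  spike <- 3000 + sample.int(50, rpois(1, 0.1 * 20 * 50), replace = TRUE) - 1
  ip <- readsFromTxOffsets(anno, "t1", c(bg, spike), len = 40, sampleId = "ip")
  ctrl <- readsFromTxOffsets(anno, "t1",
                             sample.int(10000, 100, replace = TRUE) - 1,
                             len = 40, sampleId = "ctrl")
  pc <- callPeaks(ip, ctrl, anno)
  g <- peaks(pc)
  expect_equal(length(g), 1L)
  m <- S4Vectors::mcols(g)
  expect_true(m$tsummit >= 3000 && m$tsummit < 3050)
  expect_true(m$q <= 0.05)
  expect_true(m$enrichment > 5)
})

test_that("empty control falls back to gene background with a warning", {
  anno <- toyAnnotation()
  ip <- readsFromTxOffsets(anno, "t1", rep(60:80, 10), sampleId = "ip")
  expect_warning(pc <- callPeaks(ip, NULL, anno), "control")
  expect_s4_class(pc, "PeakCall")
})

test_that("region densities equal a per-feature classification tally", {
  cfg <- simConfig(seed = 304, nGenes = 25)
  anno <- simulateAnnotation(cfg)
  clip <- simulateClip(cfg, anno)
  rs <- clip$ip[[1]]
  rd <- regionDensity(rs, anno)
  ## brute force: classify each read's 5' end independently
  g <- reads(rs)
  p5 <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
               GenomicRanges::start(g), GenomicRanges::end(g))
  lab <- classifyPosition(anno, as.character(GenomicRanges::seqnames(g)), p5 - 1)
  tall <- table(factor(lab, levels = rd$class))
  expect_equal(rd$count, as.numeric(tall))
  expect_equal(sum(rd$count), length(g))
  lens <- classLengths(anno)
  expect_equal(rd$density_per_kb[lens > 0],
               unname((as.numeric(tall) / (lens / 1000))[lens > 0]))
  ## zero-length classes report NA, not 0
  expect_true(all(is.na(rd$density_per_kb[rd$length_nt == 0])))
})

test_that("density is zero everywhere when there are no features", {
  anno <- toyAnnotation()
  rd <- regionDensity(ReadSet("empty", GRanges()), anno)
  expect_true(all(rd$count == 0))
  expect_true(all(rd$density_per_kb[rd$length_nt > 0] == 0))
})

test_that("metagene counts match the per-feature loop oracle", {
  anno <- toyAnnotation()
  ## one anchor at 5'UTR offset 0 -> bin 0 of the 5'UTR row only
  rs <- readsFromTxOffsets(anno, "t1", 0, len = 30)
  mp <- metageneProfile(rs, anno, BinScheme(50))
  expect_equal(unname(binCounts(mp)["utr5", 1]), 1)
  expect_equal(sum(binCounts(mp)), 1)
  ## aggregate bin extents cover each region exactly once here
  expect_equal(sum(binLengths(mp)["cds", ]), 300)

  cfg <- simConfig(seed = 305, nGenes = 30)
  annoS <- simulateAnnotation(cfg)
  clip <- simulateClip(cfg, annoS)
  rs2 <- clip$ip[[1]]
  mp2 <- metageneProfile(rs2, annoS, BinScheme(50))
  g <- reads(rs2)
  p5 <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
               GenomicRanges::start(g), GenomicRanges::end(g))
  want <- bruteMetageneCounts(annoS, as.character(GenomicRanges::seqnames(g)),
                              p5 - 1, as.character(GenomicRanges::strand(g)), 50)
  expect_equal(binCounts(mp2), want)
  ## conservation: every in-region anchor lands in exactly one bin
  lab <- toTranscriptCoords(annoS, as.character(GenomicRanges::seqnames(g)),
                            p5 - 1, as.character(GenomicRanges::strand(g)))
  expect_equal(sum(binCounts(mp2)), sum(!is.na(lab$region)))
})

test_that("target definition is q-thresholded and monotone", {
  cfg <- simConfig(seed = 306, nGenes = 60)
  anno <- simulateAnnotation(cfg)
  clip <- simulateClip(cfg, anno)
  pc <- callPeaks(poolReadSets(clip$ip[[1]], clip$ip[[2]]), clip$control, anno)
  t05 <- defineTargets(pc, 0.05)
  t01 <- defineTargets(pc, 0.01)
  t001 <- defineTargets(pc, 0.001)
  expect_true(all(t01 %in% t05))
  expect_true(all(t001 %in% t01))
  ## genes without any peak are never targets
  expect_true(all(t05 %in% S4Vectors::mcols(peaks(pc))$gene_id))
})

test_that("replicate correlation is 1 for identical replicates and near 0 for noise", {
  cfg <- simConfig(seed = 307, nGenes = 40)
  anno <- simulateAnnotation(cfg)
  clip <- simulateClip(cfg, anno)
  expect_equal(replicateCorrelation(clip$ip[[1]], clip$ip[[1]], anno), 1)
  ## independent placements with no shared abundance structure: use a single
  ## long transcript and window-level counting
  df <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", utr5_len = 500, cds_len = 48000,
                   utr3_len = 1500, gene_type = "protein_coding")
  longAnno <- makeTranscriptAnnotation(
    df, GRangesList(t1 = GRanges("chr1", IRanges(1, 50000))))
  set.seed(9)
  r1 <- readsFromTxOffsets(longAnno, "t1",
                           sample.int(50000, 5000, replace = TRUE) - 1)
  r2 <- readsFromTxOffsets(longAnno, "t1",
                           sample.int(50000, 5000, replace = TRUE) - 1)
  r <- replicateCorrelation(r1, r2, longAnno, window = 50)
  expect_lt(abs(r), 0.1)
  ## degenerate: no reads anywhere -> zero variance -> error
  e1 <- ReadSet("e1", GRanges()); e2 <- ReadSet("e2", GRanges())
  expect_error(replicateCorrelation(e1, e2, anno), "variance")
})
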