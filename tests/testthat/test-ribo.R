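test_that("P-site anchored footprint densities are exact on a toy gene", {
  anno <- toyAnnotation()
  ## 30 footprints whose P-site (5' + 12) lands in the CDS
  offs <- seq(50, 337, by = 10) - 12
  rs <- readsFromTxOffsets(anno, "t1", offs, len = 30)
  fd <- footprintDensity(rs, anno, psiteOffset = 12)
  expect_equal(fd$count[fd$class == "cds"], length(offs))
  expect_equal(fd$density_per_kb[fd$class == "cds"],
               length(offs) / (300 / 1000))
})

test_that("the P-site offset moves a boundary read from 5'UTR to CDS", {
  anno <- toyAnnotation()
  ## 5' end 6 nt before the CDS start (utr5 offset 44)
  rs <- readsFromTxOffsets(anno, "t1", 44, len = 30)
  d0 <- footprintDensity(rs, anno, psiteOffset = 0)
  d12 <- footprintDensity(rs, anno, psiteOffset = 12)
  expect_equal(d0$count[d0$class == "utr5"], 1)
  expect_equal(d0$count[d0$class == "cds"], 0)
  expect_equal(d12$count[d12$class == "utr5"], 0)
  expect_equal(d12$count[d12$class == "cds"], 1)
})

test_that("anchors beyond the transcript end are skipped with a message", {
  anno <- toyAnnotation()
  rs <- readsFromTxOffsets(anno, "t1", c(100, 495), len = 5)
  expect_message(fd <- footprintDensity(rs, anno, psiteOffset = 12),
                 "skipped")
  expect_equal(sum(fd$count), 1)
})

test_that("occupancy curves are normalized and reflect concentrated signal", {
  anno <- toyAnnotation()
  ## all P-sites at the first CDS nucleotide
  rs <- readsFromTxOffsets(anno, "t1", rep(50 - 12, 40), len = 30)
  oc <- occupancyCurve(rs, anno, BinScheme(20))
  d <- binDensity(oc)
  expect_equal(sum(d), 1, tolerance = 1e-9)
  expect_equal(unname(d["cds", 1]), 1)
  expect_true(all(d[, -1][-2] >= 0))
})

test_that("uniform anchors over equal-length regions give a near-flat curve", {
  df <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
                   strand = "+", utr5_len = 600, cds_len = 600,
                   utr3_len = 600, gene_type = "protein_coding")
  anno <- makeTranscriptAnnotation(
    df, GRangesList(t1 = GRanges("chr1", IRanges(1, 1800))))
  set.seed(41)
  n <- 60000
  anchors <- sample.int(1800 - 12, n, replace = TRUE) - 1 + 12
  rs <- readsFromTxOffsets(anno, "t1", anchors - 12, len = 30)
  oc <- suppressMessages(occupancyCurve(rs, anno, BinScheme(20)))
  d <- as.vector(binDensity(oc))
  expected <- 1 / 60
  ## each bin holds ~n/60 anchors; 3 MC standard errors on the proportion
  se <- sqrt(expected * (1 - expected) / n) * (60 / 60)
  ## tolerate the 12-nt cap exclusion in the first 5'UTR bin
  expect_true(all(abs(d[-1] - expected) < 3 * sqrt(expected / n) + 3 * se))
})

test_that("gene-class filtering errors when nothing is left", {
  cfg <- simConfig(seed = 308, nGenes = 20)
  anno <- simulateAnnotation(cfg)
  rb <- simulateRibo(cfg, anno, "WT")
  expect_error(
    occupancyCurve(rb, anno, BinScheme(20), geneClass = "target",
                   targets = character(0)),
    "no footprints|targets")
  expect_error(occupancyCurve(rb, anno, geneClass = "target"), "targets")
})

test_that("KS shift statistic equals the brute-force ECDF maximum", {
  expect_error(shiftTest(runif(10), runif(10)), "anchors per side")
  set.seed(13)
  for (i in 1:20) {
    nA <- sample(30:50, 1); nB <- sample(30:50, 1)
    x <- round(runif(nA), 2)  # rounding forces ties
    y <- round(runif(nB), 2)
    st <- shiftTest(x, y, region = "cds")
    expect_equal(st@D, bruteKsD(x, y), tolerance = 1e-12)
  }
  ## identical multisets: D = 0, p = 1
  x <- runif(40)
  st <- shiftTest(x, x, region = "cds")
  expect_equal(st@D, 0)
  expect_equal(st@p, 1)
})

test_that("KS detects a genuine location shift", {
  set.seed(14)
  hits <- 0
  for (i in 1:20) {
    x <- runif(1000)
    y <- pmin(runif(1000, 0.2, 1.2), 0.999999)
    if (shiftTest(x, y)@p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("condition comparison is symmetric-null for identical inputs", {
  cfg <- simConfig(seed = 309, nGenes = 40)
  anno <- simulateAnnotation(cfg)
  clip <- simulateClip(cfg, anno)
  rb <- simulateRibo(cfg, anno, "WT")
  cc <- compareConditions(list(a = rb, b = rb), anno, clip$targets)
  expect_true(all(cc$tests$D == 0))
  expect_true(all(cc$tests$p == 1))
  r <- cc$ratios
  expect_equal(r$utr5_cds_ratio[r$condition == "a"],
               r$utr5_cds_ratio[r$condition == "b"])
  expect_error(compareConditions(list(a = rb), anno, clip$targets),
               "two conditions")
  expect_error(compareConditions(list(rb, rb), anno, clip$targets), "named")
})
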