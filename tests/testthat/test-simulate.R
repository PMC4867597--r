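test_that("generator outputs are byte-identical across reruns of a seed", {
  cfg <- simConfig(seed = 1234, nGenes = 15)
  run <- function() {
    anno <- simulateAnnotation(cfg)
    clip <- simulateClip(cfg, anno)
    rb <- simulateRibo(cfg, anno, "WT")
    d <- tempfile(); dir.create(d)
    writeTranscriptTsv(anno, file.path(d, "tx.tsv"))
    writeAnnotationGtf(anno, file.path(d, "anno.gtf"))
    writeReadsBed(clip$ip[[1]], file.path(d, "ip1.bed"))
    writeReadsBed(clip$control, file.path(d, "ctrl.bed"))
    writeReadsBed(rb, file.path(d, "wt.bed"))
    ex <- simulateExpression(cfg, anno)
    writeExpressionTsv(ex$expr, file.path(d, "expr.tsv"))
    writeTransitTsv(simulateTransit(cfg), file.path(d, "tc.tsv"))
    d
  }
  d1 <- run(); d2 <- run()
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty configuration still produces valid empty artifacts", {
  cfg <- simConfig(seed = 1, nGenes = 0, nNcrna = 0, nPseudo = 0)
  anno <- simulateAnnotation(cfg)
  expect_equal(nrow(transcripts(anno)), 0L)
  f <- tempfile()
  writeTranscriptTsv(anno, f)
  a2 <- loadAnnotation(f, format = "tsv")
  expect_equal(nrow(transcripts(a2)), 0L)
  unlink(f)
})

test_that("seed is mandatory and malformed configurations are rejected", {
  expect_error(simConfig(), "seed")
  expect_error(simConfig(seed = 1, targetFraction = 2), "target fraction")
  expect_error(simConfig(seed = 1, clip = list(backgroundRate = -1)),
               "non-negative")
  expect_error(simConfig(seed = 1,
                         ribo = list(conditions = list(WT = c(0, 1)))),
               "positive")
  expect_error(simConfig(seed = 1,
                         lengths = list(cds = c(meanlog = 5, sdlog = -1))),
               "degenerate")
})

test_that("sampled CDS lengths match the configured distribution", {
  cfg <- simConfig(seed = 1357, nGenes = 1000, nNcrna = 0, nPseudo = 0)
  anno <- simulateAnnotation(cfg)
  cds <- transcripts(anno)$cds_len
  target <- exp(log(1200) + 0.5^2 / 2)  # log-normal mean
  se <- stats::sd(cds) / sqrt(length(cds))
  expect_lt(abs(mean(cds) - target), 3 * se + 3)  # +3 nt codon rounding slack
})

test_that("CLIP enrichment concentrates the configured read mass in the AUG window", {
  ## single coding gene so the in-window fraction is a clean binomial check
  cfg <- simConfig(seed = 246, nGenes = 1, nNcrna = 0, nPseudo = 0,
                   targetFraction = 1, intronProb = 0,
                   lengths = list(utr5 = c(meanlog = log(200), sdlog = 0),
                                  cds = c(meanlog = log(1200), sdlog = 0),
                                  utr3 = c(meanlog = log(400), sdlog = 0)),
                   abundanceSdlog = 0,
                   clip = list(backgroundRate = 50, nReplicates = 1))
  anno <- simulateAnnotation(cfg)
  tx <- as.data.frame(transcripts(anno))
  clip <- simulateClip(cfg, anno)
  g <- reads(clip$ip[[1]])
  expect_gt(length(g), 5e4)
  p5 <- GenomicRanges::start(g) - 1
  tc <- toTranscriptCoords(anno, "chr1", p5)
  inWin <- tc$txOffset >= tx$utr5_len - 50 & tc$txOffset < tx$utr5_len
  wantFrac <- (10 * 50) / (tx$tx_len + 9 * 50)  # fold 10 in a 50-nt window
  expect_lt(abs(mean(inWin) - wantFrac), 0.03)

  ## fold 1 collapses to the uniform null: window fraction = length fraction
  cfg0 <- simConfig(seed = 246, nGenes = 1, nNcrna = 0, nPseudo = 0,
                    targetFraction = 1, intronProb = 0,
                    lengths = list(utr5 = c(meanlog = log(200), sdlog = 0),
                                   cds = c(meanlog = log(1200), sdlog = 0),
                                   utr3 = c(meanlog = log(400), sdlog = 0)),
                    abundanceSdlog = 0,
                    clip = list(backgroundRate = 50, nReplicates = 1,
                                enrichmentFold = 1))
  clip0 <- simulateClip(cfg0, anno)
  p50 <- GenomicRanges::start(reads(clip0$ip[[1]])) - 1
  tc0 <- toTranscriptCoords(anno, "chr1", p50)
  inWin0 <- tc0$txOffset >= tx$utr5_len - 50 & tc0$txOffset < tx$utr5_len
  expect_lt(abs(mean(inWin0) - 50 / tx$tx_len), 0.03)
})

test_that("truth tables mark exactly the sampled bound genes", {
  cfg <- simConfig(seed = 97, nGenes = 50)
  anno <- simulateAnnotation(cfg)
  clip <- simulateClip(cfg, anno)
  expect_setequal(clip$truth$gene_id[clip$truth$bound], clip$targets)
  tx <- as.data.frame(transcripts(anno))
  tgtTx <- tx[tx$gene_id %in% clip$targets, ]
  expect_true(all(tgtTx$cds_len > 0))
  expect_true(all(tgtTx$utr5_len >= 20))
  expect_equal(length(clip$targets), round(0.1 * 50))
})

test_that("ribosome simulator respects condition structure and drop factor", {
  cfg <- simConfig(seed = 55, nGenes = 30,
                   ribo = list(nFootprints = 2e4, dropFactor = 0))
  anno <- simulateAnnotation(cfg)
  rb <- simulateRibo(cfg, anno, "WT")
  fd <- footprintDensity(rb, anno)
  ## drop factor 0: no 3'UTR anchors at all
  expect_equal(fd$count[fd$class == "utr3"], 0)
  expect_error(simulateRibo(cfg, anno, "nope"), "unknown condition")
})

test_that("noiseless transit courses return the configured lag exactly", {
  cfg <- simConfig(seed = 3, transit = list(cv = 0,
                                            halfTransit = c(WT = 1.25)))
  tc <- simulateTransit(cfg)
  e <- fitHalfTransitTable(tc, nBoot = 0)
  expect_equal(halfTransit(e$WT), 1.25, tolerance = 1e-10)
})
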