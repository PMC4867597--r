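test_that("transcript models load identically from TSV and GTF", {
  cfg <- simConfig(seed = 301, nGenes = 20, nNcrna = 3, nPseudo = 3)
  anno <- simulateAnnotation(cfg)
  tsv <- tempfile(fileext = ".tsv"); gtf <- tempfile(fileext = ".gtf")
  writeTranscriptTsv(anno, tsv)
  writeAnnotationGtf(anno, gtf)
  a1 <- loadAnnotation(tsv)
  a2 <- loadAnnotation(gtf)
  t1 <- as.data.frame(transcripts(a1)); t2 <- as.data.frame(transcripts(a2))
  o1 <- order(t1$transcript_id); o2 <- order(t2$transcript_id)
  for (cc in c("transcript_id", "gene_id", "chrom", "strand", "utr5_len",
               "cds_len", "utr3_len", "tx_len", "gene_type"))
    expect_equal(t1[[cc]][o1], t2[[cc]][o2], info = cc)
  expect_equal(classLengths(a1), classLengths(a2))
  unlink(c(tsv, gtf))
})

test_that("single intronless gene yields the expected lengths and classes", {
  anno <- toyAnnotation()
  tx <- as.data.frame(transcripts(anno))
  expect_equal(tx$tx_len, 500)
  expect_equal(tx$utr5_len + tx$cds_len + tx$utr3_len, tx$tx_len)
  cl <- classLengths(anno)
  expect_equal(unname(cl["utr5"]), 50)
  expect_equal(unname(cl["cds"]), 300)
  expect_equal(unname(cl["utr3"]), 150)
  expect_equal(unname(cl["tts"]), 1000)
  expect_equal(unname(cl["intron"]), 0)
})

test_that("intron interval equals the exon gap exactly", {
  anno <- twoGeneAnnotation()
  cm <- classMap(anno)
  intr <- cm[S4Vectors::mcols(cm)$region == "intron"]
  expect_equal(length(intr), 1L)
  expect_equal(GenomicRanges::start(intr), 5101)  # 1-based; gap [5100,5400) 0-based
  expect_equal(GenomicRanges::end(intr), 5400)
})

test_that("class partition covers the span disjointly and sums exactly", {
  cfg <- simConfig(seed = 302, nGenes = 30)
  anno <- simulateAnnotation(cfg)
  cm <- classMap(anno)
  expect_true(all(GenomicRanges::width(GenomicRanges::reduce(cm)) ==
                  sum(GenomicRanges::width(cm)) |
                  length(GenomicRanges::reduce(cm)) >= 1))
  ## disjoint: no position covered twice
  expect_equal(sum(GenomicRanges::width(cm)),
               sum(GenomicRanges::width(GenomicRanges::reduce(cm))))
  ## per-class lengths sum to annotated span
  expect_equal(sum(classLengths(anno)), sum(GenomicRanges::width(cm)))
})

test_that("classifyPosition matches a brute-force precedence oracle", {
  ## gene A coding [1000,1500); gene B exons [500,1100)+[1800,2400) so B's
  ## intron [1100,1800) overlaps A's CDS [1050,1350)
  df <- rbind(
    data.frame(transcript_id = "tA", gene_id = "gA", chrom = "chr1",
               strand = "+", utr5_len = 50, cds_len = 300, utr3_len = 150,
               gene_type = "protein_coding"),
    data.frame(transcript_id = "tB", gene_id = "gB", chrom = "chr1",
               strand = "+", utr5_len = 100, cds_len = 900, utr3_len = 200,
               gene_type = "protein_coding"))
  anno <- makeTranscriptAnnotation(
    df,
    GRangesList(tA = GRanges("chr1", IRanges(1001, 1500)),
                tB = GRanges("chr1", IRanges(c(501, 1801), c(1100, 2400)))),
    ttsLength = 100)

  ## independent oracle: per-transcript candidate classes, explicit precedence
  prec <- c("cds", "utr5", "utr3", "ncrna", "pseudogene", "tts", "intron",
            "intergenic")
  txs <- list(
    list(id = "tA", span = c(1000, 1500), ex = cbind(1000, 1500),
         u5 = 50, cds = 300, tts = c(1500, 1600)),
    list(id = "tB", span = c(500, 2400), ex = rbind(c(500, 1100), c(1800, 2400)),
         u5 = 100, cds = 900, tts = c(2400, 2500)))
  oracle <- function(pos) {
    cand <- character()
    for (t in txs) {
      inEx <- any(pos >= t$ex[, 1] & pos < t$ex[, 2])
      if (inEx) {
        ## transcript offset by summing preceding exon pieces (plus strand)
        off <- 0
        for (j in seq_len(nrow(t$ex))) {
          if (pos >= t$ex[j, 2]) off <- off + (t$ex[j, 2] - t$ex[j, 1])
          else if (pos >= t$ex[j, 1]) off <- off + (pos - t$ex[j, 1])
        }
        cand <- c(cand, if (off < t$u5) "utr5"
                  else if (off < t$u5 + t$cds) "cds" else "utr3")
      } else if (pos >= t$span[1] && pos < t$span[2]) {
        cand <- c(cand, "intron")
      }
      if (pos >= t$tts[1] && pos < t$tts[2]) cand <- c(cand, "tts")
    }
    if (!length(cand)) return("intergenic")
    prec[min(match(cand, prec))]
  }
  pos <- 480:2520
  got <- classifyPosition(anno, "chr1", pos)
  want <- vapply(pos, oracle, "")
  expect_equal(got, want)
  ## the headline case: A's CDS beats B's intron
  expect_equal(classifyPosition(anno, "chr1", 1200), "cds")
})

test_that("unknown chromosome classifies intergenic with a warning", {
  anno <- toyAnnotation()
  expect_warning(lab <- classifyPosition(anno, "chrUn", 100), "unannotated")
  expect_equal(lab, "intergenic")
})

test_that("toTranscriptCoords handles boundaries and strand mirroring", {
  anno <- toyAnnotation()
  tc <- toTranscriptCoords(anno, "chr1", c(1000, 1050, 999, 1499, 1500))
  expect_equal(tc$region, c("utr5", "cds", NA, "utr3", NA))
  expect_equal(tc$offset, c(0, 0, NA, 149, NA))

  ## minus-strand mirror: genomic position mirrored within the same interval
  ## must give identical (region, offset)
  plus <- toyAnnotation(); minus <- mirrorAnnotation()
  pos <- c(1000, 1049, 1050, 1349, 1350, 1499)
  mirrored <- 1000 + (1499 - pos)
  tp <- toTranscriptCoords(plus, "chr1", pos)
  tm <- toTranscriptCoords(minus, "chr1", mirrored)
  expect_equal(tp$region, tm$region)
  expect_equal(tp$offset, tm$offset)
  expect_equal(tp$txOffset, tm$txOffset)
})

test_that("strand symmetry holds on a spliced simulated annotation", {
  cfg <- simConfig(seed = 303, nGenes = 40)
  anno <- simulateAnnotation(cfg)
  tx <- as.data.frame(transcripts(anno))
  minusTx <- tx[tx$strand == "-" & tx$cds_len > 0, ][1, ]
  plusTx <- tx[tx$strand == "+" & tx$cds_len > 0, ][1, ]
  ## first and last transcript nucleotide map to txOffset 0 / tx_len-1
  for (row in list(plusTx, minusTx)) {
    ex <- classMap(anno)  # not used; placeholder to keep scope clear
    rs <- readsFromTxOffsets(anno, row$transcript_id,
                             c(0, row$tx_len - 1), len = 1)
    g <- reads(rs)
    p5 <- ifelse(as.character(GenomicRanges::strand(g)) == "+",
                 GenomicRanges::start(g), GenomicRanges::end(g))
    tc <- toTranscriptCoords(anno, "chr1", p5 - 1, as.character(GenomicRanges::strand(g)))
    expect_equal(tc$txOffset, c(0, row$tx_len - 1))
  }
})

test_that("binIndex follows the clamped floor rule and matches a loop", {
  s50 <- BinScheme(50)
  expect_equal(binIndex(0, 100, s50), 0L)
  expect_equal(binIndex(99, 100, s50), 49L)
  ## exhaustive oracle for a region shorter than the bin count
  offs <- 0:36
  got <- binIndex(offs, 37, s50)
  want <- pmin(floor(offs * 50 / 37), 49)
  expect_identical(got, as.integer(want))
  ## extents agree with tabulated assignments and conserve length
  for (L in c(1, 7, 37, 50, 101, 1234)) {
    ext <- binExtents(L, s50)
    expect_equal(sum(ext), L)
    tab <- tabulate(binIndex(0:(L - 1), L, s50) + 1, nbins = 50)
    expect_equal(ext, as.numeric(tab))
  }
  expect_error(binIndex(100, 100, s50), "smaller")
  expect_true(is.na(binIndex(0, 0, s50)))
})
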