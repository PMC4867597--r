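## In-code fixtures shared across the suite. All genomic positions handed to
## package functions are 0-based half-open; GRanges built here are 1-based
## closed (the package's internal convention).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

## one intronless plus-strand gene: genomic [1000, 1500) 0-based,
## utr5 50 / cds 300 / utr3 150
toyTxdf <- function() {
  data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
             strand = "+", utr5_len = 50, cds_len = 300, utr3_len = 150,
             gene_type = "protein_coding", stringsAsFactors = FALSE)
}

toyAnnotation <- function(ttsLength = 1000) {
  makeTranscriptAnnotation(
    toyTxdf(),
    GRangesList(t1 = GRanges("chr1", IRanges(1001, 1500))),
    ttsLength = ttsLength)
}

## minus-strand mirror of the toy gene occupying the same genomic interval
mirrorAnnotation <- function(ttsLength = 1000) {
  df <- toyTxdf()
  df$strand <- "-"
  makeTranscriptAnnotation(
    df, GRangesList(t1 = GRanges("chr1", IRanges(1001, 1500))),
    ttsLength = ttsLength)
}

## two-exon minus-strand gene plus the toy gene, on separate loci
twoGeneAnnotation <- function(ttsLength = 1000) {
  df <- rbind(toyTxdf(),
              data.frame(transcript_id = "t2", gene_id = "g2", chrom = "chr1",
                         strand = "-", utr5_len = 40, cds_len = 120,
                         utr3_len = 40, gene_type = "protein_coding",
                         stringsAsFactors = FALSE))
  ## t2: 200 nt spliced over two 100-nt exons with a 300-nt intron,
  ## genomic [5000, 5100) + [5400, 5500) 0-based
  makeTranscriptAnnotation(
    df,
    GRangesList(t1 = GRanges("chr1", IRanges(1001, 1500)),
                t2 = GRanges("chr1", IRanges(c(5001, 5401), c(5100, 5500)))),
    ttsLength = ttsLength)
}

## reads on a transcript given 0-based tx offsets of the 5' ends, via the
## public TSV reader (keeps tests on the exported surface)
readsFromTxOffsets <- function(anno, txId, offsets, len = 30,
                               sampleId = "s") {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tpos5\tlength",
               sprintf("%s\t%d\t%d", txId, as.integer(offsets),
                       as.integer(len))), f)
  on.exit(unlink(f))
  readReadsTsv(f, anno, sampleId = sampleId)
}

## independent ECDF-based two-sample KS statistic (brute force over pooled
## points), used as the oracle against shiftTest
bruteKsD <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

## independent per-feature metagene binning oracle: the annotation is
## re-read from the package's own TSV and every feature is placed by plain
## block arithmetic (no shared code with the pipeline's mappers)
bruteMetageneCounts <- function(anno, chrom, pos, strand, nBins) {
  f <- tempfile(fileext = ".tsv")
  writeTranscriptTsv(anno, f)
  tab <- read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  unlink(f)
  blocks <- lapply(strsplit(tab$blocks, ","), function(b) {
    se <- do.call(rbind, strsplit(b, "-"))
    cbind(as.numeric(se[, 1]), as.numeric(se[, 2]))   # 0-based half-open
  })
  counts <- matrix(0, 3, nBins,
                   dimnames = list(c("utr5", "cds", "utr3"), NULL))
  for (i in seq_along(pos)) {
    for (t in seq_len(nrow(tab))) {
      if (tab$chrom[t] != chrom[i]) next
      if (strand[i] != "*" && tab$strand[t] != strand[i]) next
      bl <- blocks[[t]]
      hit <- which(pos[i] >= bl[, 1] & pos[i] < bl[, 2])
      if (!length(hit)) next
      ## offset in plus orientation, then flip for minus strand
      w <- bl[, 2] - bl[, 1]
      offPlus <- sum(w[seq_len(hit - 1)]) + (pos[i] - bl[hit, 1])
      off <- if (tab$strand[t] == "+") offPlus else sum(w) - 1 - offPlus
      if (tab$cds_len[t] == 0) break      # non-coding: no mRNA regions
      u5 <- tab$utr5_len[t]; cd <- tab$cds_len[t]; u3 <- tab$utr3_len[t]
      if (off < u5) { reg <- "utr5"; ro <- off; L <- u5 }
      else if (off < u5 + cd) { reg <- "cds"; ro <- off - u5; L <- cd }
      else { reg <- "utr3"; ro <- off - u5 - cd; L <- u3 }
      b <- min(floor(ro * nBins / L), nBins - 1)
      counts[reg, b + 1] <- counts[reg, b + 1] + 1
      break
    }
  }
  counts
}
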