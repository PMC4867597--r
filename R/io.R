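#' @include AllClasses.R annotation.R
NULL

#' Construct a ReadSet
#'
#' @param sampleId sample label.
#' @param reads `GRanges` of stranded read intervals.
#' @return A [ReadSet-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 140), strand = "+")
#' ReadSet("ip_rep1", gr)
#' @export
ReadSet <- function(sampleId, reads) {
  new("ReadSet", sampleId = as.character(sampleId), reads = reads,
      totalMapped = length(reads))
}

## ---- anchoring ---------------------------------------------------------

## One anchor nucleotide per read: the 5' end plus `offset` nt walked along
## the *transcript* (P-site assignment). Reads mapping to no transcript are
## offset along the genome on their own strand. Reads whose anchor would fall
## beyond the transcript 3' end are skipped (and counted).
## Returns: GRanges points with mcols transcript_id/txOffset/region/
## regionOffset/regionLength, plus the skip count, as a list.
anchorPositions <- function(rs, anno, offset = 0) {
  stopifnot(is(rs, "ReadSet"), is(anno, "TranscriptAnnotation"))
  g <- reads(rs)
  if (length(g) == 0L) {
    pts <- GRanges()
    mcols(pts) <- DataFrame(transcript_id = character(), txOffset = numeric(),
                            region = character(), regionOffset = numeric(),
                            regionLength = numeric())
    return(list(points = pts, nSkipped = 0L))
  }
  plus <- as.character(strand(g)) == "+"
  p5 <- ifelse(plus, start(g), end(g))
  pts <- GRanges(seqnames(g), IRanges(p5, width = 1), strand = strand(g))
  m <- .mapToTx(anno, pts)
  tx <- anno@transcripts
  i <- match(m$transcript_id, tx$transcript_id)
  txOff <- m$offset + offset
  skip <- !is.na(txOff) & txOff >= tx$tx_len[i]
  nSkipped <- sum(skip)
  if (nSkipped)
    message(nSkipped, " read(s) skipped: anchor beyond transcript end")
  keepTx <- !is.na(txOff) & !skip
  anchorPos <- p5
  ## transcript-mapped anchors: walk the offset along the spliced transcript
  if (offset > 0 && any(keepTx)) {
    anchorPos[keepTx] <- .txOffsetsToGenomic(anno, m$transcript_id[keepTx],
                                             txOff[keepTx])
  }
  ## unmapped reads: plain genomic offset along the read strand
  unm <- is.na(m$transcript_id)
  if (offset > 0 && any(unm))
    anchorPos[unm] <- ifelse(plus[unm], p5[unm] + offset, p5[unm] - offset)
  keep <- !skip
  out <- GRanges(seqnames(g)[keep], IRanges(anchorPos[keep], width = 1),
                 strand = strand(g)[keep])
  txOffK <- txOff[keep]; iK <- i[keep]
  reg <- .regionOfOffset(tx$utr5_len[iK], tx$cds_len[iK], txOffK)
  regionLength <- ifelse(reg$region == "utr5", tx$utr5_len[iK],
                         ifelse(reg$region == "cds", tx$cds_len[iK],
                                tx$utr3_len[iK]))
  ## non-coding transcripts carry no mRNA region decomposition
  noncoding <- !is.na(iK) & tx$cds_len[iK] == 0
  reg$region[noncoding] <- NA_character_
  mcols(out)$transcript_id <- m$transcript_id[keep]
  mcols(out)$txOffset <- txOffK
  mcols(out)$region <- reg$region
  mcols(out)$regionOffset <- ifelse(is.na(reg$region), NA_real_, reg$regionOffset)
  mcols(out)$regionLength <- ifelse(is.na(reg$region), NA_real_, regionLength)
  list(points = out, nSkipped = nSkipped)
}

## bulk transcript-offset -> genomic (1-based), grouped by transcript
.txOffsetsToGenomic <- function(anno, txIds, offsets) {
  ei <- .exonLookup(anno)
  res <- numeric(length(txIds))
  for (id in unique(txIds)) {
    sel <- which(txIds == id)
    e <- ei[[id]]
    j <- findInterval(offsets[sel], e$cum)
    pl <- e$strand[j] == "+"
    res[sel] <- ifelse(pl, e$start[j] + (offsets[sel] - e$cum[j]),
                       e$end[j] - (offsets[sel] - e$cum[j]))
  }
  res
}

## ---- readers -----------------------------------------------------------

#' Read aligned intervals from BED6
#'
#' @param path BED6 file (0-based half-open on disk; rtracklayer converts).
#' @param sampleId sample label (default: file name without extension).
#' @return A [ReadSet-class].
#' @export
readReadsBed <- function(path, sampleId = sub("\\.bed$", "", basename(path))) {
  g <- rtracklayer::import(path, format = "BED")
  mcols(g) <- NULL
  ReadSet(sampleId, g)
}

#' Read per-transcript reads from TSV
#'
#' Columns `transcript_id`, `pos5` (0-based transcript coordinate of the read
#' 5' end) and `length`; intervals are projected onto the genome (clipped at
#' the exon boundary containing the 5' end) using the annotation.
#'
#' @param path TSV path.
#' @param anno a [TranscriptAnnotation-class].
#' @param sampleId sample label.
#' @return A [ReadSet-class].
#' @export
readReadsTsv <- function(path, anno,
                         sampleId = sub("\\.tsv$", "", basename(path))) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "pos5", "length")
  miss <- base::setdiff(need, colnames(tab))
  if (length(miss))
    stop("reads TSV is missing column(s): ", paste(miss, collapse = ", "))
  g <- .txReadsToGenomic(anno, tab$transcript_id, tab$pos5, tab$length)
  ReadSet(sampleId, g)
}

## project reads given by (transcript, 5'-end offset, length) to genomic
## intervals, clipped at the transcript end and at the exon block holding
## the 5' end; assembles a single GRanges at the end for speed
.txReadsToGenomic <- function(anno, txIds, pos5, len) {
  tx <- anno@transcripts
  ei <- .exonLookup(anno)
  n <- length(txIds)
  chrom <- character(n); gs <- numeric(n); wlen <- numeric(n); st <- character(n)
  for (id in unique(txIds)) {
    sel <- which(txIds == id)
    ti <- match(id, tx$transcript_id)
    if (is.na(ti)) stop("unknown transcript in reads: ", id)
    e <- ei[[id]]
    o <- pos5[sel]
    if (any(o < 0 | o >= tx$tx_len[ti]))
      stop("read 5' offset outside transcript ", id)
    j <- findInterval(o, e$cum)
    wl <- pmin(len[sel], tx$tx_len[ti] - o, e$cum[j] + e$w[j] - o)
    pl <- e$strand[j] == "+"
    gs[sel] <- ifelse(pl, e$start[j] + (o - e$cum[j]),
                      e$end[j] - (o - e$cum[j]) - wl + 1)
    wlen[sel] <- wl
    chrom[sel] <- e$chrom[j]
    st[sel] <- e$strand[j]
  }
  if (n == 0L) return(GRanges())
  GRanges(chrom, IRanges(gs, width = wlen), strand = st)
}

## plain-vector per-transcript exon lookup (exons ordered by cumStart),
## memoised on the annotation object's environment-free slots via a local
## cache keyed by object identity within a single call chain
.exonLookup <- function(anno) {
  idx <- anno@exonIndex
  ids <- mcols(idx)$txId
  cums <- mcols(idx)$cumStart
  chrom <- as.character(seqnames(idx))
  st <- as.character(strand(idx))
  sidx <- split(seq_along(idx), ids)
  lapply(sidx, function(s) {
    s <- s[order(cums[s])]
    list(cum = cums[s], w = width(idx)[s], start = start(idx)[s],
         end = end(idx)[s], chrom = chrom[s], strand = st[s])
  })
}

## ---- writers (fixed formatting so identical inputs give identical bytes) --

.fmtInt <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Write a ReadSet as BED6
#'
#' @param rs a [ReadSet-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeReadsBed <- function(rs, path) {
  g <- reads(rs)
  lines <- sprintf("%s\t%s\t%s\t%s\t0\t%s",
                   as.character(seqnames(g)), .fmtInt(start(g) - 1L),
                   .fmtInt(end(g)), sampleId(rs), as.character(strand(g)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the transcript models as the simplified TSV
#'
#' @param anno a [TranscriptAnnotation-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTranscriptTsv <- function(anno, path) {
  tx <- as.data.frame(transcripts(anno))
  hdr <- paste(c("transcript_id", "gene_id", "chrom", "strand", "utr5_len",
                 "cds_len", "utr3_len", "blocks", "gene_type"), collapse = "\t")
  lines <- hdr
  if (nrow(tx)) {
    blocks <- vapply(tx$transcript_id, function(id) {
      b <- anno@exons[[id]]
      paste(sprintf("%s-%s", .fmtInt(start(b) - 1L), .fmtInt(end(b))),
            collapse = ",")
    }, "")
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                              tx$transcript_id, tx$gene_id, tx$chrom, tx$strand,
                              .fmtInt(tx$utr5_len), .fmtInt(tx$cds_len),
                              .fmtInt(tx$utr3_len), blocks, tx$gene_type))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the transcript models as GTF
#'
#' Emits `exon` and `CDS` features with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes. CDS features include the stop codon (the CDS
#' length convention used throughout the package).
#'
#' @inheritParams writeTranscriptTsv
#' @return Invisibly, `path`.
#' @export
writeAnnotationGtf <- function(anno, path) {
  tx <- as.data.frame(transcripts(anno))
  lines <- character()
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    attr <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                    tx$gene_id[i], id, tx$gene_type[i])
    ex <- anno@exons[[id]]
    lines <- c(lines, sprintf("%s\triboclip\texon\t%s\t%s\t.\t%s\t.\t%s",
                              tx$chrom[i], .fmtInt(start(ex)), .fmtInt(end(ex)),
                              tx$strand[i], attr))
    if (tx$cds_len[i] > 0) {
      cdsG <- .projectTxIntervalRaw(ex, tx$strand[i], tx$utr5_len[i],
                                    tx$utr5_len[i] + tx$cds_len[i])
      cdsG <- sort(cdsG)
      lines <- c(lines, sprintf("%s\triboclip\tCDS\t%s\t%s\t.\t%s\t0\t%s",
                                tx$chrom[i], .fmtInt(start(cdsG)),
                                .fmtInt(end(cdsG)), tx$strand[i], attr))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write called peaks as BED6+ TSV
#'
#' BED-style 0-based half-open coordinates with extra columns `summit`
#' (0-based genomic), `ip_count`, `expected`, `enrichment`, `p`, `q`,
#' `gene_id`.
#'
#' @param pc a [PeakCall-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writePeaksBed <- function(pc, path) {
  g <- peaks(pc)
  m <- mcols(g)
  hdr <- paste(c("chrom", "start", "end", "name", "score", "strand", "summit",
                 "ip_count", "expected", "enrichment", "p", "q", "gene_id"),
               collapse = "\t")
  lines <- hdr
  if (length(g)) {
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\tpeak_%d\t0\t%s\t%s\t%s\t%.6g\t%.6g\t%.6g\t%.6g\t%s",
      as.character(seqnames(g)), .fmtInt(start(g) - 1L), .fmtInt(end(g)),
      seq_along(g), as.character(strand(g)), .fmtInt(m$summit - 1L),
      .fmtInt(m$ip_count), m$expected, m$enrichment, m$p, m$q, m$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a metagene profile or occupancy curve as TSV
#'
#' Long format: `region`, `bin`, plus `count`, `bin_length`, `density` for
#' [MetageneProfile-class] or `relative_density` for [OccupancyCurve-class].
#'
#' @param x a `MetageneProfile` or `OccupancyCurve`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeProfileTsv <- function(x, path) {
  n <- nBins(x)
  if (is(x, "MetageneProfile")) {
    df <- data.frame(region = rep(REGIONS, each = n),
                     bin = rep(seq_len(n) - 1L, 3L),
                     count = as.vector(t(binCounts(x))),
                     bin_length = as.vector(t(binLengths(x))),
                     density = as.vector(t(binDensity(x))))
  } else if (is(x, "OccupancyCurve")) {
    df <- data.frame(region = rep(REGIONS, each = n),
                     bin = rep(seq_len(n) - 1L, 3L),
                     relative_density = as.vector(t(binDensity(x))))
  } else stop("x must be a MetageneProfile or OccupancyCurve")
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Expects a header with `gene_id` followed by sample columns named
#' `<condition>_<replicate>`; returns the abundance matrix and the
#' per-column condition labels.
#'
#' @param path TSV path.
#' @return list with `expr` (genes x samples matrix) and `condition`.
#' @export
readExpressionTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(tab)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  list(expr = m, condition = sub("_[^_]*$", "", colnames(m)))
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples numeric matrix with gene ids as rownames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeExpressionTsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transit-time labeling courses
#'
#' Expects columns `condition`, `replicate`, `time_min`, `pms_cpm`,
#' `prs_cpm`.
#'
#' @param path TSV path.
#' @return data.frame of the time courses.
#' @export
readTransitTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "time_min", "pms_cpm", "prs_cpm")
  miss <- base::setdiff(need, colnames(tab))
  if (length(miss))
    stop("transit TSV is missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Write transit-time labeling courses
#'
#' @param tc data.frame as returned by [simulateTransit()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTransitTsv <- function(tc, path) {
  utils::write.table(format(tc, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
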