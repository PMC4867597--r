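#' @include AllClasses.R AllGenerics.R
#' @importFrom GenomicRanges findOverlaps reduce setdiff union sort shift
#'   resize flank GRangesList
#' @importFrom GenomeInfoDb seqlevels
#' @importFrom BiocGenerics unstrand
#' @importFrom S4Vectors queryHits subjectHits Rle runValue
#' @importFrom IRanges IRanges
#' @importFrom stats setNames
NULL

CLASS_PRECEDENCE <- c("cds", "utr5", "utr3", "ncrna", "pseudogene",
                      "tts", "intron")

## ---- internal coordinate machinery -------------------------------------
## GRanges are 1-based closed internally; every numeric position or offset
## exposed by the API and every file interface is 0-based half-open.

.exonIndex <- function(txdf, exons) {
  if (nrow(txdf) == 0L)
    return(GRanges(txId = character(), cumStart = numeric()))
  grl <- exons[txdf$transcript_id]
  w <- lapply(grl, width)
  cum <- mapply(function(wi, st) {
    if (st == "+") c(0, cumsum(wi))[seq_along(wi)]
    else rev(c(0, cumsum(rev(wi)))[seq_along(wi)])
  }, w, txdf$strand, SIMPLIFY = FALSE)
  gr <- unlist(grl, use.names = FALSE)
  mcols(gr)$txId <- rep(txdf$transcript_id, lengths(w))
  mcols(gr)$cumStart <- unlist(cum, use.names = FALSE)
  strand(gr) <- rep(txdf$strand, lengths(w))
  gr
}

## anchors: GRanges of width-1 points. Returns per-point transcript id and
## 0-based transcript offset (NA when the point hits no exon of a transcript
## on the same strand; '*' queries match either strand). First hit in
## transcript-table order wins when transcripts overlap.
.mapToTx <- function(anno, points) {
  idx <- anno@exonIndex
  hits <- findOverlaps(points, idx, ignore.strand = TRUE)
  if (length(hits)) {
    qs <- as.character(strand(points))[queryHits(hits)]
    ss <- as.character(strand(idx))[subjectHits(hits)]
    hits <- hits[qs == "*" | qs == ss]
  }
  txId <- rep(NA_character_, length(points))
  offset <- rep(NA_real_, length(points))
  if (length(hits)) {
    first <- !duplicated(queryHits(hits))
    q <- queryHits(hits)[first]
    s <- subjectHits(hits)[first]
    pos <- start(points)[q]
    plus <- as.character(strand(idx)[s]) == "+"
    off <- ifelse(plus,
                  mcols(idx)$cumStart[s] + (pos - start(idx)[s]),
                  mcols(idx)$cumStart[s] + (end(idx)[s] - pos))
    txId[q] <- mcols(idx)$txId[s]
    offset[q] <- off
  }
  data.frame(transcript_id = txId, offset = offset)
}

## region of a transcript offset; tx is a row-subset lookup into transcripts
.regionOfOffset <- function(u5, cds, offset) {
  region <- ifelse(offset < u5, "utr5",
                   ifelse(offset < u5 + cds, "cds", "utr3"))
  regionOffset <- ifelse(region == "utr5", offset,
                         ifelse(region == "cds", offset - u5,
                                offset - u5 - cds))
  data.frame(region = region, regionOffset = regionOffset)
}

## project transcript-coordinate interval [a, b) (0-based half-open) of one
## transcript onto genomic ranges
.projectTxInterval <- function(anno, txId, a, b) {
  idx <- anno@exonIndex[mcols(anno@exonIndex)$txId == txId]
  if (b <= a || length(idx) == 0L) return(GRanges())
  cum <- mcols(idx)$cumStart
  w <- width(idx)
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    lo <- max(a, cum[j]); hi <- min(b, cum[j] + w[j])
    if (hi <= lo) next
    if (as.character(strand(idx)[j]) == "+") {
      gs <- start(idx)[j] + (lo - cum[j]); ge <- start(idx)[j] + (hi - cum[j]) - 1
    } else {
      ge <- end(idx)[j] - (lo - cum[j]); gs <- end(idx)[j] - (hi - cum[j]) + 1
    }
    out[[j]] <- GRanges(seqnames(idx)[j], IRanges(gs, ge), strand = strand(idx)[j])
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) GRanges() else sort(do.call(c, out), ignore.strand = TRUE)
}

## vectorized transcript offset -> genomic 1-based position for one transcript
.txOffsetToGenomic <- function(anno, txId, offsets) {
  idx <- anno@exonIndex[mcols(anno@exonIndex)$txId == txId]
  cum <- mcols(idx)$cumStart
  w <- width(idx)
  j <- vapply(offsets, function(o) which(o >= cum & o < cum + w)[1], 1L)
  plus <- as.character(strand(idx)[j]) == "+"
  ifelse(plus, start(idx)[j] + (offsets - cum[j]), end(idx)[j] - (offsets - cum[j]))
}

.buildClassMap <- function(txdf, exons, ttsLength) {
  empty <- GRanges()
  mcols(empty)$region <- character()
  if (nrow(txdf) == 0L)
    return(list(map = empty,
                lengths = setNames(numeric(length(REGION_LABELS)),
                                   names(REGION_LABELS))))
  grl <- exons[txdf$transcript_id]
  allEx <- unstrand(unlist(grl, use.names = FALSE))
  txSpan <- unstrand(unlist(range(grl), use.names = FALSE))

  exStarts <- lapply(grl, start)
  exEnds <- lapply(grl, end)
  exChroms <- vapply(grl, function(g) as.character(seqnames(g))[1], "")

  coding <- which(txdf$cds_len > 0)
  regionRanges <- list(utr5 = GRanges(), cds = GRanges(), utr3 = GRanges())
  if (length(coding)) {
    acc <- list(utr5 = list(), cds = list(), utr3 = list())
    for (i in coding) {
      u5 <- txdf$utr5_len[i]; cd <- txdf$cds_len[i]; tl <- txdf$tx_len[i]
      bounds <- list(utr5 = c(0, u5), cds = c(u5, u5 + cd), utr3 = c(u5 + cd, tl))
      for (r in REGIONS) {
        co <- .projectCoords(exStarts[[i]], exEnds[[i]], txdf$strand[i],
                             bounds[[r]][1], bounds[[r]][2])
        if (length(co$start))
          acc[[r]][[length(acc[[r]]) + 1L]] <-
            cbind(co$start, co$end, i)
      }
    }
    for (r in REGIONS) {
      if (!length(acc[[r]])) next
      m <- do.call(rbind, acc[[r]])
      regionRanges[[r]] <- GRanges(exChroms[m[, 3]], IRanges(m[, 1], m[, 2]))
    }
  }
  ncrna <- unstrand(unlist(grl[txdf$gene_type == "ncRNA"], use.names = FALSE))
  pseudo <- unstrand(unlist(grl[txdf$gene_type == "pseudogene"], use.names = FALSE))
  tts <- if (ttsLength > 0) {
    sp <- unlist(range(grl), use.names = FALSE)
    strand(sp) <- txdf$strand
    g <- flank(sp, width = ttsLength, start = FALSE)
    start(g) <- pmax(start(g), 1L)
    unstrand(g[width(g) > 0])
  } else GRanges()
  introns <- GenomicRanges::setdiff(reduce(txSpan), reduce(allEx))

  ordered <- list(cds = regionRanges$cds, utr5 = regionRanges$utr5,
                  utr3 = regionRanges$utr3, ncrna = ncrna,
                  pseudogene = pseudo, tts = tts, intron = introns)
  span <- reduce(range(c(reduce(txSpan), reduce(tts)), ignore.strand = TRUE))
  taken <- GRanges()
  pieces <- list()
  for (cls in CLASS_PRECEDENCE) {
    g <- reduce(ordered[[cls]])
    if (!length(g)) next
    g <- GenomicRanges::setdiff(g, taken)
    if (!length(g)) next
    mcols(g)$region <- cls
    pieces[[cls]] <- g
    taken <- reduce(GenomicRanges::union(taken, g))
  }
  inter <- GenomicRanges::setdiff(span, taken)
  if (length(inter)) {
    mcols(inter)$region <- "intergenic"
    pieces[["intergenic"]] <- inter
  }
  map <- sort(do.call(c, unname(pieces)), ignore.strand = TRUE)
  lens <- setNames(numeric(length(REGION_LABELS)), names(REGION_LABELS))
  got <- tapply(width(map), mcols(map)$region, sum)
  lens[names(got)] <- got
  list(map = map, lengths = lens)
}

## project tx-coordinate interval [a, b) onto genomic (start, end) pairs,
## given one transcript's exon starts/ends (ascending genomic order)
.projectCoords <- function(bStart, bEnd, strand, a, b) {
  if (b <= a || !length(bStart)) return(list(start = numeric(), end = numeric()))
  w <- bEnd - bStart + 1
  cum <- if (strand == "+") c(0, cumsum(w))[seq_along(w)]
         else rev(c(0, cumsum(rev(w)))[seq_along(w)])
  gs <- numeric(); ge <- numeric()
  for (j in seq_along(bStart)) {
    lo <- max(a, cum[j]); hi <- min(b, cum[j] + w[j])
    if (hi <= lo) next
    if (strand == "+") {
      gs <- c(gs, bStart[j] + (lo - cum[j])); ge <- c(ge, bStart[j] + (hi - cum[j]) - 1)
    } else {
      ge <- c(ge, bEnd[j] - (lo - cum[j])); gs <- c(gs, bEnd[j] - (hi - cum[j]) + 1)
    }
  }
  list(start = gs, end = ge)
}

## GRanges form, used where per-transcript volume is tiny (GTF writer)
.projectTxIntervalRaw <- function(blocks, strand, a, b) {
  co <- .projectCoords(start(blocks), end(blocks), strand, a, b)
  if (!length(co$start)) return(GRanges())
  GRanges(as.character(seqnames(blocks))[1], IRanges(co$start, co$end))
}

## ---- construction ------------------------------------------------------

#' Construct a TranscriptAnnotation from parsed components
#'
#' Lower-level constructor used by [loadAnnotation()] and the simulator. One
#' canonical transcript per gene is retained (longest CDS, then longest
#' transcript, then lexicographically smallest transcript id).
#'
#' @param txdf data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `utr5_len`, `cds_len`, `utr3_len`, `gene_type`.
#' @param exons named `GRangesList` of exon blocks per transcript (ascending
#'   genomic order).
#' @param ttsLength nt downstream of each transcript end classified as TTS
#'   (default 1000).
#' @return A [TranscriptAnnotation-class] object.
#' @export
makeTranscriptAnnotation <- function(txdf, exons, ttsLength = 1000) {
  txdf <- as.data.frame(txdf, stringsAsFactors = FALSE)
  if (is.null(txdf$gene_type)) txdf$gene_type <- "protein_coding"
  if (nrow(txdf)) {
    txdf$tx_len <- as.numeric(sum(width(exons[txdf$transcript_id])))
    ## canonical transcript per gene
    o <- order(txdf$gene_id, -txdf$cds_len, -txdf$tx_len, txdf$transcript_id)
    txdf <- txdf[o, , drop = FALSE]
    txdf <- txdf[!duplicated(txdf$gene_id), , drop = FALSE]
    rownames(txdf) <- NULL
    exons <- exons[txdf$transcript_id]
    bad <- which(txdf$cds_len > 0 &
                 txdf$utr5_len + txdf$cds_len + txdf$utr3_len != txdf$tx_len)
    if (length(bad))
      stop("region lengths do not sum to exon total for transcript(s): ",
           paste(txdf$transcript_id[bad], collapse = ", "))
  } else {
    txdf$tx_len <- numeric(0)
  }
  cm <- .buildClassMap(txdf, exons, ttsLength)
  new("TranscriptAnnotation",
      transcripts = DataFrame(txdf),
      exons = exons,
      exonIndex = .exonIndex(txdf, exons),
      classMap = cm$map,
      classLengths = cm$lengths,
      ttsLength = ttsLength)
}

#' Load a transcript annotation from GTF/GFF or a transcript TSV
#'
#' GTF/GFF input is read with rtracklayer; `exon` and `CDS` features grouped
#' by `transcript_id` define the transcript models, with UTR lengths derived
#' from the CDS position inside the spliced transcript. The simplified TSV
#' format has columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#' `utr5_len`, `cds_len`, `utr3_len`, `blocks` (comma-separated
#' `start-end` exon intervals, 0-based half-open) and optionally `gene_type`.
#' The resulting model is independent of record order.
#'
#' @param path file path (`.gtf`/`.gff`/`.gff3` or `.tsv`).
#' @param format `"auto"` (by extension), `"gtf"` or `"tsv"`.
#' @param ttsLength nt downstream of transcript ends classified as TTS.
#' @return A [TranscriptAnnotation-class] object.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\tgene_id\tchrom\tstrand\tutr5_len\tcds_len\tutr3_len\tblocks",
#'              "t1\tg1\tchr1\t+\t50\t300\t150\t1000-1500"), tsv)
#' anno <- loadAnnotation(tsv)
#' transcripts(anno)
#' @export
loadAnnotation <- function(path, format = c("auto", "gtf", "tsv"),
                           ttsLength = 1000) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?|gff)$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  }
  if (format == "gtf") .loadGtf(path, ttsLength) else .loadTsv(path, ttsLength)
}

.loadTsv <- function(path, ttsLength) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = "character")
  need <- c("transcript_id", "gene_id", "chrom", "strand",
            "utr5_len", "cds_len", "utr3_len", "blocks")
  miss <- base::setdiff(need, colnames(tab))
  if (length(miss))
    stop("transcript TSV is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("utr5_len", "cds_len", "utr3_len")) tab[[cc]] <- as.numeric(tab[[cc]])
  if (nrow(tab) == 0L)
    return(makeTranscriptAnnotation(
      data.frame(transcript_id = character(), gene_id = character(),
                 chrom = character(), strand = character(),
                 utr5_len = numeric(), cds_len = numeric(),
                 utr3_len = numeric(), gene_type = character()),
      GRangesList(), ttsLength))
  blocks <- lapply(seq_len(nrow(tab)), function(i) {
    parts <- strsplit(tab$blocks[i], ",", fixed = TRUE)[[1]]
    se <- t(vapply(strsplit(parts, "-", fixed = TRUE), function(x) {
      if (length(x) != 2L || anyNA(suppressWarnings(as.numeric(x))))
        stop(sprintf("malformed blocks field at line %d of %s: '%s'",
                     i + 1L, path, tab$blocks[i]))
      as.numeric(x)
    }, numeric(2)))
    if (any(se[, 2] <= se[, 1]))
      stop(sprintf("empty exon block at line %d of %s", i + 1L, path))
    ## 0-based half-open on file -> 1-based closed GRanges
    sort(GRanges(tab$chrom[i], IRanges(se[, 1] + 1, se[, 2])))
  })
  names(blocks) <- tab$transcript_id
  txdf <- data.frame(
    transcript_id = tab$transcript_id, gene_id = tab$gene_id,
    chrom = tab$chrom, strand = tab$strand,
    utr5_len = tab$utr5_len, cds_len = tab$cds_len, utr3_len = tab$utr3_len,
    gene_type = if ("gene_type" %in% colnames(tab)) tab$gene_type
                else ifelse(tab$cds_len > 0, "protein_coding", "ncRNA"),
    stringsAsFactors = FALSE)
  makeTranscriptAnnotation(txdf, GRangesList(blocks), ttsLength)
}

.loadGtf <- function(path, ttsLength) {
  gr <- rtracklayer::import(path)
  if (!all(c("type", "gene_id", "transcript_id") %in% colnames(mcols(gr))))
    stop("GTF must carry type, gene_id and transcript_id attributes: ", path)
  ex <- gr[mcols(gr)$type == "exon"]
  cds <- gr[mcols(gr)$type == "CDS"]
  if (length(ex) == 0L)
    stop("no exon records found in ", path)
  exl <- S4Vectors::split(ex, mcols(ex)$transcript_id)
  exl <- GRangesList(lapply(exl, function(g) sort(GRanges(seqnames(g), IRanges(start(g), end(g))))))
  txids <- names(exl)
  meta <- mcols(ex)[match(txids, mcols(ex)$transcript_id), ]
  firstEx <- ex[match(txids, mcols(ex)$transcript_id)]
  gtype <- if ("gene_biotype" %in% colnames(meta)) as.character(meta$gene_biotype)
           else NA_character_
  rows <- lapply(seq_along(txids), function(i) {
    id <- txids[i]
    blocks <- exl[[id]]
    st <- as.character(strand(firstEx[i]))
    tl <- sum(width(blocks))
    ci <- cds[mcols(cds)$transcript_id == id]
    if (length(ci)) {
      ## CDS must be inside exons
      if (sum(width(GenomicRanges::intersect(
            reduce(GRanges(seqnames(ci), IRanges(start(ci), end(ci)))),
            reduce(blocks)))) != sum(width(reduce(GRanges(seqnames(ci), IRanges(start(ci), end(ci)))))))
        stop("CDS outside exon bounds for transcript ", id, " in ", path)
      cdsLen <- sum(width(ci))
      ## transcript offset of the CDS 5'-most base
      p5 <- if (st == "+") min(start(ci)) else max(end(ci))
      off <- .txOffsetOfGenomic(blocks, st, p5)
      u5 <- off
      u3 <- tl - u5 - cdsLen
      if (u3 < 0) stop("CDS extends past transcript end for ", id, " in ", path)
      data.frame(transcript_id = id, gene_id = as.character(meta$gene_id[i]),
                 chrom = as.character(seqnames(firstEx[i])), strand = st,
                 utr5_len = u5, cds_len = cdsLen, utr3_len = u3,
                 gene_type = if (is.na(gtype[i])) "protein_coding" else gtype[i],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = id, gene_id = as.character(meta$gene_id[i]),
                 chrom = as.character(seqnames(firstEx[i])), strand = st,
                 utr5_len = 0, cds_len = 0, utr3_len = 0,
                 gene_type = if (is.na(gtype[i])) "ncRNA" else gtype[i],
                 stringsAsFactors = FALSE)
    }
  })
  txdf <- do.call(rbind, rows)
  o <- order(txdf$transcript_id)
  makeTranscriptAnnotation(txdf[o, , drop = FALSE], exl[txdf$transcript_id[o]],
                           ttsLength)
}

## transcript offset (0-based) of a genomic position within given blocks
.txOffsetOfGenomic <- function(blocks, strand, pos) {
  w <- width(blocks)
  cum <- if (strand == "+") c(0, cumsum(w))[seq_along(w)]
         else rev(c(0, cumsum(rev(w)))[seq_along(w)])
  j <- which(pos >= start(blocks) & pos <= end(blocks))
  if (!length(j)) stop("position not inside exon blocks")
  j <- j[1]
  if (strand == "+") cum[j] + (pos - start(blocks)[j])
  else cum[j] + (end(blocks)[j] - pos)
}

## ---- classification and binning ---------------------------------------

#' Classify genomic positions into annotation region classes
#'
#' Assigns each 0-based genomic position to exactly one region class from the
#' disjoint class partition (precedence CDS > 5'-UTR > 3'-UTR > ncRNA >
#' pseudogene > TTS > intron > intergenic). Positions outside the annotated
#' span, or on an unannotated chromosome (with a warning), are intergenic.
#'
#' @param anno a [TranscriptAnnotation-class].
#' @param chrom character vector of chromosome names.
#' @param pos numeric vector of 0-based genomic positions.
#' @param strand strand of the query (accepted for interface symmetry; the
#'   class partition is strand-blind).
#' @return Character vector of class labels (`utr5`, `cds`, `utr3`, `ncrna`,
#'   `pseudogene`, `tts`, `intron`, `intergenic`).
#' @export
classifyPosition <- function(anno, chrom, pos, strand = "*") {
  stopifnot(is(anno, "TranscriptAnnotation"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep("intergenic", n)
  known <- GenomeInfoDb::seqlevels(anno@classMap)
  unk <- !(chrom %in% known)
  if (any(unk))
    warning("position(s) on unannotated chromosome(s): ",
            paste(unique(chrom[unk]), collapse = ", "), " -> intergenic")
  if (all(unk)) return(out)
  q <- GRanges(chrom[!unk], IRanges(pos[!unk] + 1, width = 1))
  hits <- findOverlaps(q, anno@classMap)
  lab <- rep("intergenic", sum(!unk))
  lab[queryHits(hits)] <- mcols(anno@classMap)$region[subjectHits(hits)]
  out[!unk] <- lab
  out
}

#' Map genomic positions to transcript region coordinates
#'
#' Converts 0-based genomic positions to (region, offset-in-region) on the
#' canonical transcript whose exon blocks contain them. Offsets count 0-based
#' from the region's 5' end in transcript orientation; minus-strand
#' transcripts reverse the coordinate axis. Positions hitting no exon return
#' NA rows.
#'
#' @inheritParams classifyPosition
#' @param strand per-position strand; reads are matched to transcripts on the
#'   same strand (`"*"` matches either).
#' @return data.frame with columns `transcript_id`, `region` (`utr5`, `cds`,
#'   `utr3`), `offset` (0-based within region), `txOffset` (0-based within
#'   transcript).
#' @export
toTranscriptCoords <- function(anno, chrom, pos, strand = "*") {
  stopifnot(is(anno, "TranscriptAnnotation"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  pts <- GRanges(chrom, IRanges(pos + 1, width = 1), strand = strand)
  m <- .mapToTx(anno, pts)
  tx <- anno@transcripts
  i <- match(m$transcript_id, tx$transcript_id)
  reg <- .regionOfOffset(tx$utr5_len[i], tx$cds_len[i], m$offset)
  ## non-coding transcripts carry no mRNA region decomposition
  bad <- is.na(m$offset) | (!is.na(i) & tx$cds_len[i] == 0)
  data.frame(transcript_id = m$transcript_id,
             region = ifelse(bad, NA_character_, reg$region),
             offset = ifelse(bad, NA_real_, reg$regionOffset),
             txOffset = m$offset)
}

#' Metagene bin assignment for a within-region offset
#'
#' Deterministic floor rule: `floor(offset * nBins / regionLength)`, clamped
#' to the last bin. Returns NA (a skipped feature) when `regionLength` is 0.
#'
#' @param offset 0-based offset(s) within the region; must be `< regionLength`.
#' @param regionLength region length(s) in nt.
#' @param scheme a [BinScheme-class].
#' @return Integer bin indices in `[0, nBins - 1]`.
#' @examples
#' binIndex(0, 100, BinScheme(50))
#' binIndex(99, 100, BinScheme(50))
#' @export
binIndex <- function(offset, regionLength, scheme) {
  stopifnot(is(scheme, "BinScheme"))
  n <- scheme@nBins
  if (any(!is.na(offset) & !is.na(regionLength) & offset >= regionLength &
          regionLength > 0))
    stop("offset must be smaller than regionLength")
  b <- floor(as.numeric(offset) * n / as.numeric(regionLength))
  b <- pmin(b, n - 1)
  b[!is.na(regionLength) & regionLength == 0] <- NA
  as.integer(b)
}

#' Nucleotide extent of each metagene bin for a region length
#'
#' Number of 0-based offsets in `[0, regionLength)` mapping to each bin under
#' the floor rule; extents sum to `regionLength`.
#'
#' @inheritParams binIndex
#' @return Numeric vector of length `nBins`.
#' @export
binExtents <- function(regionLength, scheme) {
  stopifnot(is(scheme, "BinScheme"))
  n <- scheme@nBins
  L <- as.numeric(regionLength)
  b <- seq_len(n)
  ceiling(b * L / n) - ceiling((b - 1) * L / n)
}
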