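#' @include AllClasses.R annotation.R io.R
#' @importFrom stats ppois p.adjust cor
#' @importFrom IRanges coverage
NULL

#' Poisson upper-tail p-value for a window count
#'
#' `P(X >= count)` for `X ~ Poisson(expected)` — the enrichment test behind
#' the peak caller, exposed for reuse and for oracle checks. Clamped below at
#' the smallest positive double.
#'
#' @param count observed IP read count (non-negative integer).
#' @param expected expected count under the background model (> 0).
#' @return Upper-tail probability in (0, 1].
#' @examples
#' poissonPeakPvalue(10, 2)
#' @export
poissonPeakPvalue <- function(count, expected) {
  pmax(ppois(count - 1, expected, lower.tail = FALSE), .Machine$double.xmin)
}

#' Call peaks from CLIP IP reads against a control library
#'
#' Sliding windows over spliced transcript coordinates are scored with a
#' Poisson upper-tail test. Each window's expected count is the maximum of
#' (i) the control count in the window scaled by the library-size ratio,
#' (ii) the transcript-level IP background rate times the window length, and
#' (iii) a pseudocount — so enrichment must beat both the matched control and
#' the transcript's own average coverage. Benjamini-Hochberg correction runs
#' over all tested windows; overlapping or adjacent significant windows are
#' merged and each merged peak's summit is the transcript position of maximal
#' per-base read coverage (ties resolved 5'-most).
#'
#' Reads are anchored at their 5' ends. An empty control switches the caller
#' to transcript-background-only mode with a warning.
#'
#' @param ip [ReadSet-class] of IP reads (replicates pooled upstream with
#'   [poolReadSets()]).
#' @param control [ReadSet-class] of the IgG/input control, or `NULL`.
#' @param anno a [TranscriptAnnotation-class].
#' @param window window size in nt (default 50).
#' @param step step between window starts in nt (default 25).
#' @param pseudocount minimum expected count (default 1).
#' @param fdr BH q-value threshold defining significant windows (default 0.05).
#' @param minCount minimum IP count for a window to be tested (default 5).
#' @param keepWindows if `TRUE`, the per-window test table (`tx`, `gene`,
#'   `ws`, `we`, `cnt`, `expected`, `p`, `q`) is kept in
#'   `peakParams(x)$windows` (used for FDR-calibration studies).
#' @return A [PeakCall-class].
#' @export
callPeaks <- function(ip, control, anno, window = 50, step = 25,
                      pseudocount = 1, fdr = 0.05, minCount = 5,
                      keepWindows = FALSE) {
  stopifnot(is(ip, "ReadSet"), is(anno, "TranscriptAnnotation"))
  if (totalMapped(ip) == 0L) stop("IP library is empty")
  haveControl <- !is.null(control) && totalMapped(control) > 0L
  if (!haveControl)
    warning("empty control: falling back to transcript-background-only mode")
  libRatio <- if (haveControl) totalMapped(ip) / totalMapped(control) else NA_real_

  tx <- anno@transcripts
  ipA <- anchorPositions(ip, anno, offset = 0)$points
  ipByTx <- split(mcols(ipA)$txOffset, mcols(ipA)$transcript_id)
  ctrlByTx <- if (haveControl) {
    ctA <- anchorPositions(control, anno, offset = 0)$points
    split(mcols(ctA)$txOffset, mcols(ctA)$transcript_id)
  } else list()
  ## read intervals in transcript coordinates for summit coverage
  ## (anchorPositions with offset 0 keeps all reads, in input order)
  readTx <- data.frame(tx = mcols(ipA)$transcript_id,
                       start = mcols(ipA)$txOffset,
                       len = width(reads(ip)))
  readTx <- readTx[!is.na(readTx$tx), , drop = FALSE]

  win <- list()
  for (i in seq_len(nrow(tx))) {
    id <- tx$transcript_id[i]
    L <- tx$tx_len[i]
    o <- ipByTx[[id]]
    if (is.null(o)) o <- numeric()
    ws <- if (L <= window) 0 else seq(0, L - window, by = step)
    wEnd <- pmin(ws + window, L)
    so <- sort(o)
    cnt <- findInterval(wEnd - 0.5, so) - findInterval(ws - 0.5, so)
    bg <- length(o) / L * (wEnd - ws)
    expCtrl <- 0
    if (haveControl) {
      oc <- sort(ctrlByTx[[id]])
      if (length(oc))
        expCtrl <- (findInterval(wEnd - 0.5, oc) - findInterval(ws - 0.5, oc)) * libRatio
    }
    expected <- pmax(expCtrl, bg, pseudocount)
    win[[i]] <- data.frame(tx = id, gene = tx$gene_id[i], ws = ws, we = wEnd,
                           cnt = cnt, expected = expected)
  }
  win <- do.call(rbind, win)
  tested <- win[win$cnt >= minCount, , drop = FALSE]
  params <- list(window = as.integer(window), step = as.integer(step),
                 pseudocount = pseudocount, fdr = fdr,
                 minCount = as.integer(minCount), libRatio = libRatio)
  emptyPeaks <- function() {
    g <- GRanges()
    mcols(g) <- DataFrame(summit = integer(), ip_count = integer(),
                          expected = numeric(), enrichment = numeric(),
                          p = numeric(), q = numeric(), gene_id = character(),
                          transcript_id = character(), tstart = integer(),
                          tend = integer(), tsummit = integer())
    new("PeakCall", peaks = g, params = params, nTested = nrow(tested))
  }
  if (nrow(tested) > 0L) {
    tested$p <- poissonPeakPvalue(tested$cnt, tested$expected)
    tested$q <- p.adjust(tested$p, method = "BH")
  }
  if (keepWindows) params$windows <- tested
  if (nrow(tested) == 0L) return(emptyPeaks())
  sig <- tested[tested$q <= fdr, , drop = FALSE]
  if (nrow(sig) == 0L) return(emptyPeaks())

  rows <- list()
  for (id in unique(sig$tx)) {
    s <- sig[sig$tx == id, , drop = FALSE]
    i <- match(id, tx$transcript_id)
    L <- tx$tx_len[i]
    merged <- IRanges::reduce(IRanges(s$ws + 1, s$we))  # 1-based tx coords
    o <- sort(ipByTx[[id]])
    r <- readTx[readTx$tx == id, , drop = FALSE]
    cov <- coverage(IRanges(r$start + 1, pmin(r$start + r$len, L)), width = L)
    covv <- as.numeric(cov)
    for (k in seq_along(merged)) {
      a <- start(merged)[k] - 1; b <- end(merged)[k]   # [a, b) 0-based
      ipc <- sum(o >= a & o < b)
      bgexp <- length(o) / L * (b - a)
      ctexp <- 0
      if (haveControl) {
        oc <- ctrlByTx[[id]]
        if (!is.null(oc)) ctexp <- sum(oc >= a & oc < b) * libRatio
      }
      expec <- max(ctexp, bgexp, pseudocount)
      seg <- covv[(a + 1):b]
      tsummit <- a + which.max(seg) - 1            # ties: 5'-most
      ## the merged peak inherits its best constituent window's p/q (keeps
      ## q monotone in p across the peak set)
      inWin <- s$ws < b & s$we > a
      best <- which.min(s$p[inWin])
      rows[[length(rows) + 1L]] <- data.frame(
        tx = id, gene = tx$gene_id[i], tstart = a, tend = b,
        tsummit = tsummit, ip_count = ipc, expected = expec,
        p = s$p[inWin][best], q = s$q[inWin][best])
    }
  }
  pk <- do.call(rbind, rows)
  ## back to genomic coordinates
  gl <- vector("list", nrow(pk))
  summitG <- .txOffsetsToGenomic(anno, pk$tx, pk$tsummit)
  for (k in seq_len(nrow(pk))) {
    pr <- .projectTxInterval(anno, pk$tx[k], pk$tstart[k], pk$tend[k])
    gl[[k]] <- GRanges(seqnames(pr)[1],
                       IRanges(min(start(pr)), max(end(pr))),
                       strand = strand(pr)[1])
  }
  g <- do.call(c, gl)
  mcols(g) <- DataFrame(summit = as.integer(summitG),
                        ip_count = as.integer(pk$ip_count),
                        expected = pk$expected,
                        enrichment = pk$ip_count / pk$expected,
                        p = pk$p, q = pk$q, gene_id = pk$gene,
                        transcript_id = pk$tx, tstart = as.integer(pk$tstart),
                        tend = as.integer(pk$tend),
                        tsummit = as.integer(pk$tsummit))
  o <- order(as.character(seqnames(g)), start(g))
  new("PeakCall", peaks = g[o], params = params, nTested = nrow(tested))
}

#' Pool read sets (e.g. CLIP replicates before peak calling)
#'
#' @param ... [ReadSet-class] objects.
#' @param sampleId label for the pooled set.
#' @return A [ReadSet-class].
#' @export
poolReadSets <- function(..., sampleId = "pooled") {
  rs <- list(...)
  stopifnot(length(rs) >= 1L, all(vapply(rs, is, TRUE, "ReadSet")))
  ReadSet(sampleId, do.call(c, lapply(rs, reads)))
}

#' Per-genomic-class feature density (features per kb)
#'
#' Anchors each feature at a single nucleotide (peak summit, or read 5' end
#' plus `psiteOffset`), classifies it against the region-class partition, and
#' divides per-class counts by class length in kb. Classes of zero annotated
#' length get `NA` density, never 0.
#'
#' @param features a [PeakCall-class] or [ReadSet-class].
#' @param anno a [TranscriptAnnotation-class].
#' @param psiteOffset anchor offset from the read 5' end (ignored for peaks).
#' @return data.frame with columns `class`, `count`, `length_nt`,
#'   `density_per_kb`.
#' @export
regionDensity <- function(features, anno, psiteOffset = 0) {
  stopifnot(is(anno, "TranscriptAnnotation"))
  if (is(features, "PeakCall")) {
    g <- peaks(features)
    anchors <- data.frame(chrom = as.character(seqnames(g)),
                          pos = mcols(g)$summit - 1)  # 0-based
  } else if (is(features, "ReadSet")) {
    a <- anchorPositions(features, anno, offset = psiteOffset)$points
    anchors <- data.frame(chrom = as.character(seqnames(a)),
                          pos = start(a) - 1)
  } else stop("features must be a PeakCall or ReadSet")
  cls <- if (nrow(anchors))
    classifyPosition(anno, anchors$chrom, anchors$pos) else character()
  lens <- classLengths(anno)
  cnt <- setNames(numeric(length(lens)), names(lens))
  if (length(cls)) {
    tt <- table(cls)
    cnt[names(tt)] <- tt
  }
  data.frame(class = names(lens), count = as.numeric(cnt),
             length_nt = as.numeric(lens),
             density_per_kb = ifelse(lens > 0, cnt / (lens / 1000), NA),
             row.names = NULL)
}

#' Region-normalized metagene profile of peaks or reads
#'
#' Features are anchored (summits for peaks; read 5' ends plus `psiteOffset`
#' for reads), mapped to (region, bin) on their transcript by the floor rule,
#' and densities reported as features per kb of aggregate bin extent.
#' Transcripts lacking a region (e.g. `utr5_len == 0`) are excluded from that
#' region's aggregate only.
#'
#' @inheritParams regionDensity
#' @param scheme a [BinScheme-class] (default 50 bins per region).
#' @return A [MetageneProfile-class].
#' @export
metageneProfile <- function(features, anno, scheme = BinScheme(50),
                            psiteOffset = 0) {
  stopifnot(is(anno, "TranscriptAnnotation"), is(scheme, "BinScheme"))
  if (is(features, "PeakCall")) {
    g <- peaks(features)
    tx <- anno@transcripts
    i <- match(mcols(g)$transcript_id, tx$transcript_id)
    reg <- .regionOfOffset(tx$utr5_len[i], tx$cds_len[i], mcols(g)$tsummit)
    feat <- data.frame(region = reg$region, offset = reg$regionOffset,
                       regionLength = ifelse(reg$region == "utr5", tx$utr5_len[i],
                                      ifelse(reg$region == "cds", tx$cds_len[i],
                                             tx$utr3_len[i])))
  } else if (is(features, "ReadSet")) {
    a <- anchorPositions(features, anno, offset = psiteOffset)$points
    m <- mcols(a)
    feat <- data.frame(region = m$region, offset = m$regionOffset,
                       regionLength = m$regionLength)
    feat <- feat[!is.na(feat$region), , drop = FALSE]
  } else stop("features must be a PeakCall or ReadSet")

  n <- scheme@nBins
  counts <- matrix(0, 3, n, dimnames = list(REGIONS, NULL))
  if (nrow(feat)) {
    b <- binIndex(feat$offset, feat$regionLength, scheme)
    keep <- !is.na(b)
    tt <- table(factor(feat$region[keep], levels = REGIONS),
                factor(b[keep], levels = 0:(n - 1)))
    counts[] <- as.numeric(tt)
  }
  tx <- anno@transcripts
  coding <- tx[tx$cds_len > 0, , drop = FALSE]
  binLen <- matrix(0, 3, n, dimnames = list(REGIONS, NULL))
  nGenes <- setNames(numeric(3), REGIONS)
  regLens <- list(utr5 = coding$utr5_len, cds = coding$cds_len,
                  utr3 = coding$utr3_len)
  for (r in REGIONS) {
    Ls <- regLens[[r]][regLens[[r]] > 0]
    nGenes[r] <- length(Ls)
    if (length(Ls))
      binLen[r, ] <- Reduce(`+`, lapply(Ls, binExtents, scheme = scheme))
  }
  dens <- ifelse(binLen > 0, counts / (binLen / 1000), NA)
  new("MetageneProfile", scheme = scheme, counts = counts, binLengths = binLen,
      density = dens, nGenes = nGenes, nFeatures = sum(counts))
}

#' Define the target gene set from called peaks
#'
#' A gene is a target iff it carries at least one merged peak with
#' `q <= qThreshold`.
#'
#' @param pc a [PeakCall-class].
#' @param qThreshold BH q-value cutoff (default 0.05).
#' @return Character vector of target gene ids (sorted, unique).
#' @export
defineTargets <- function(pc, qThreshold = 0.05) {
  stopifnot(is(pc, "PeakCall"))
  m <- mcols(peaks(pc))
  sort(unique(m$gene_id[!is.na(m$q) & m$q <= qThreshold]))
}

#' Replicate reproducibility as Pearson correlation of binned coverage
#'
#' Reads of each replicate are anchored at their 5' ends and counted on a
#' common grid — per transcript by default (the unit on which biological
#' reproducibility of CLIP signal is abundance-driven), or in fixed
#' non-overlapping windows tiling every transcript when `window` is given.
#' The correlation is computed on log2(count + 1).
#'
#' @param rep1,rep2 [ReadSet-class] replicates.
#' @param anno a [TranscriptAnnotation-class].
#' @param window optional tiling window size in nt; `NULL` (default) uses
#'   whole transcripts as the grid.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(rep1, rep2, anno, window = NULL) {
  stopifnot(is(rep1, "ReadSet"), is(rep2, "ReadSet"))
  tx <- anno@transcripts
  cnt <- function(rs) {
    a <- anchorPositions(rs, anno, offset = 0)$points
    byTx <- split(mcols(a)$txOffset, mcols(a)$transcript_id)
    if (is.null(window)) {
      vapply(tx$transcript_id, function(id) length(byTx[[id]]), 0)
    } else {
      unlist(lapply(seq_len(nrow(tx)), function(i) {
        L <- tx$tx_len[i]
        ws <- seq(0, L - 1, by = window)
        we <- pmin(ws + window, L)
        o <- sort(byTx[[tx$transcript_id[i]]])
        if (is.null(o)) return(numeric(length(ws)))
        findInterval(we - 0.5, o) - findInterval(ws - 0.5, o)
      }), use.names = FALSE)
    }
  }
  v1 <- log2(cnt(rep1) + 1)
  v2 <- log2(cnt(rep2) + 1)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance in binned coverage; correlation undefined")
  cor(v1, v2)
}
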