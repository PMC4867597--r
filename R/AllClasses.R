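#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand "strand<-"
#'   start "start<-" end "end<-" width
#' @importFrom IRanges IRanges
NULL

REGIONS <- c("utr5", "cds", "utr3")

REGION_LABELS <- c(
  utr5 = "5'-UTR", cds = "CDS", utr3 = "3'-UTR", intron = "intron",
  tts = "TTS", ncrna = "ncRNA", pseudogene = "pseudogene",
  intergenic = "intergenic"
)

#' Fixed-bin scheme for region-normalized metagene profiles
#'
#' Each mRNA region (5'-UTR, CDS, 3'-UTR) is rescaled to `nBins` bins; a
#' position at 0-based offset `o` in a region of length `L` falls in bin
#' `floor(o * nBins / L)`, clamped to `nBins - 1`. CLIP metagene profiles use
#' 50 bins per region; condition-comparison occupancy curves use 20.
#'
#' @slot nBins integer, number of bins per region.
#' @export
setClass("BinScheme", representation(nBins = "integer"))

setValidity("BinScheme", function(object) {
  if (length(object@nBins) != 1L || is.na(object@nBins) || object@nBins < 1L)
    return("nBins must be a single positive integer")
  TRUE
})

#' @param nBins number of bins per region (positive integer).
#' @return A `BinScheme` object.
#' @rdname BinScheme-class
#' @examples
#' BinScheme(50)
#' @export
BinScheme <- function(nBins) new("BinScheme", nBins = as.integer(nBins))

#' Transcript models plus the genomic region-class partition
#'
#' Holds one canonical transcript model per gene (5'-UTR/CDS/3'-UTR lengths and
#' ordered exon blocks) together with a disjoint partition of the annotated
#' genomic span into region classes (CDS, 5'-UTR, 3'-UTR, ncRNA, pseudogene,
#' TTS, intron, intergenic) under a fixed precedence. All interval arithmetic
#' is GRanges-backed (1-based closed internally; file interfaces are 0-based
#' half-open).
#'
#' @slot transcripts `DataFrame` with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `utr5_len`, `cds_len`, `utr3_len`, `tx_len`,
#'   `gene_type`.
#' @slot exons `GRangesList`, exon blocks per transcript in ascending genomic
#'   order, named by transcript id.
#' @slot exonIndex `GRanges`, one range per exon with `txId` and `cumStart`
#'   (0-based transcript coordinate of the exon's 5'-most base in transcript
#'   orientation) for fast genome/transcript coordinate mapping.
#' @slot classMap `GRanges`, disjoint intervals covering the annotated span,
#'   with metadata column `region`.
#' @slot classLengths named numeric, total nucleotides per region class.
#' @slot ttsLength numeric, length of the downstream window classified as TTS.
#' @export
setClass("TranscriptAnnotation", representation(
  transcripts  = "DataFrame",
  exons        = "GRangesList",
  exonIndex    = "GRanges",
  classMap     = "GRanges",
  classLengths = "numeric",
  ttsLength    = "numeric"
))

setValidity("TranscriptAnnotation", function(object) {
  tx <- object@transcripts
  msgs <- character()
  need <- c("transcript_id", "gene_id", "chrom", "strand",
            "utr5_len", "cds_len", "utr3_len", "tx_len", "gene_type")
  if (!all(need %in% colnames(tx)))
    return(paste("transcripts must have columns:", paste(need, collapse = ", ")))
  if (nrow(tx) > 0) {
    blockLens <- as.numeric(sum(width(object@exons[tx$transcript_id])))
    if (!all(abs(blockLens - tx$tx_len) < 0.5))
      msgs <- c(msgs, "tx_len must equal the exon block total per transcript")
    coding <- tx$cds_len > 0
    tot <- tx$utr5_len + tx$cds_len + tx$utr3_len
    if (any(coding) && !all(tot[coding] == tx$tx_len[coding]))
      msgs <- c(msgs, "region lengths must sum to tx_len for coding transcripts")
    if (any(tx$utr5_len < 0) || any(tx$utr3_len < 0) || any(tx$cds_len < 0))
      msgs <- c(msgs, "region lengths must be non-negative")
  }
  if (length(object@classLengths) &&
      any(!names(object@classLengths) %in% names(REGION_LABELS)))
    msgs <- c(msgs, "unknown region class in classLengths")
  if (length(msgs)) msgs else TRUE
})

#' Strand-aware read or footprint interval set
#'
#' A labelled set of aligned single-end read intervals (CLIP reads or ribosome
#' footprints) in genomic coordinates. Analyses anchor each read at a single
#' nucleotide (the 5' end, plus a P-site offset for footprints).
#'
#' @slot sampleId character scalar sample label.
#' @slot reads `GRanges` of read intervals (strand required).
#' @slot totalMapped integer, library size (equals the record count).
#' @export
setClass("ReadSet", representation(
  sampleId    = "character",
  reads       = "GRanges",
  totalMapped = "integer"
))

setValidity("ReadSet", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be a single string")
  if (object@totalMapped != length(object@reads))
    return("totalMapped must equal the number of read records")
  if (any(strand(object@reads) == "*"))
    return("reads must be stranded")
  TRUE
})

#' Called peak set with enrichment statistics
#'
#' Merged significant windows from control-subtracted sliding-window Poisson
#' peak calling. Peaks are non-overlapping per transcript; each carries its
#' summit (position of maximal per-base read coverage), IP count, expected
#' count under the background model, fold enrichment, Poisson upper-tail p and
#' Benjamini-Hochberg q, and the gene it annotates to.
#'
#' @slot peaks `GRanges` with metadata columns `summit`, `ip_count`,
#'   `expected`, `enrichment`, `p`, `q`, `gene_id`, `transcript_id`,
#'   `tstart`, `tend`, `tsummit` (transcript-coordinate extent, 0-based
#'   half-open).
#' @slot params list of caller parameters (window, step, pseudocount, fdr,
#'   minCount, libRatio).
#' @slot nTested integer, number of windows entering BH correction.
#' @export
setClass("PeakCall", representation(
  peaks   = "GRanges",
  params  = "list",
  nTested = "integer"
))

setValidity("PeakCall", function(object) {
  m <- mcols(object@peaks)
  need <- c("summit", "ip_count", "expected", "enrichment", "p", "q", "gene_id")
  if (!all(need %in% colnames(m)))
    return(paste("peaks must carry metadata:", paste(need, collapse = ", ")))
  if (length(object@peaks)) {
    o <- order(m$p)
    if (is.unsorted(m$q[o])) return("q must be non-decreasing in p")
    if (any(m$p <= 0 | m$p > 1)) return("p must lie in (0, 1]")
  }
  TRUE
})

#' Region-normalized metagene profile
#'
#' Feature counts, aggregate bin extents and densities (features per kb) over
#' the binned 5'-UTR/CDS/3'-UTR axis, summed across genes.
#'
#' @slot scheme the `BinScheme` used.
#' @slot counts 3 x nBins matrix of feature counts (rows utr5, cds, utr3).
#' @slot binLengths 3 x nBins matrix of total nucleotide extent per bin.
#' @slot density 3 x nBins matrix, `counts / (binLengths/1000)` (NA where a
#'   bin has zero aggregate extent).
#' @slot nGenes named numeric, genes contributing per region.
#' @slot nFeatures numeric, features assigned.
#' @export
setClass("MetageneProfile", representation(
  scheme     = "BinScheme",
  counts     = "matrix",
  binLengths = "matrix",
  density    = "matrix",
  nGenes     = "numeric",
  nFeatures  = "numeric"
))

setValidity("MetageneProfile", function(object) {
  n <- object@scheme@nBins
  for (s in c("counts", "binLengths", "density")) {
    m <- slot(object, s)
    if (!all(dim(m) == c(3L, n)) || !identical(rownames(m), REGIONS))
      return(sprintf("%s must be a 3 x nBins matrix with rows utr5/cds/utr3", s))
  }
  if (sum(object@counts) != object@nFeatures)
    return("counts must sum to nFeatures")
  TRUE
})

#' Relative ribosome occupancy curve
#'
#' Per-bin footprint densities over the three mRNA regions, normalized so the
#' whole 3-region curve sums to 1, making curves comparable across
#' sequencing depths and conditions.
#'
#' @slot condition condition label (e.g. vector, WT, G325E).
#' @slot geneClass one of `all`, `target`, `non-target`.
#' @slot scheme the `BinScheme` used (20 or 50 bins per region).
#' @slot density 3 x nBins matrix of relative densities summing to 1.
#' @slot nFootprints integer count of anchored footprints used.
#' @export
setClass("OccupancyCurve", representation(
  condition   = "character",
  geneClass   = "character",
  scheme      = "BinScheme",
  density     = "matrix",
  nFootprints = "numeric"
))

setValidity("OccupancyCurve", function(object) {
  if (any(object@density < 0, na.rm = TRUE)) return("densities must be >= 0")
  if (abs(sum(object@density, na.rm = TRUE) - 1) > 1e-9)
    return("relative densities must sum to 1")
  TRUE
})

#' Two-sample occupancy shift test result
#'
#' Kolmogorov-Smirnov comparison of within-region footprint positions
#' (normalized to [0,1) per transcript) between two samples or conditions.
#'
#' @slot region region tested (`utr5`, `cds` or `utr3`).
#' @slot comparison character(2), labels of the two sides.
#' @slot D KS statistic in [0, 1].
#' @slot p asymptotic p-value in (0, 1].
#' @slot nA,nB anchors per side.
#' @export
setClass("ShiftTestResult", representation(
  region = "character", comparison = "character",
  D = "numeric", p = "numeric", nA = "numeric", nB = "numeric"
))

setValidity("ShiftTestResult", function(object) {
  if (object@D < 0 || object@D > 1) return("D must lie in [0, 1]")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  TRUE
})

#' Ribosome half-transit time estimate
#'
#' Dual ordinary-least-squares fit to paired PMS (total nascent polypeptide)
#' and PRS (released polypeptide) labeling time courses. The half-transit time
#' is the difference of the two time-axis intercepts; a bootstrap over time
#' points supplies the confidence interval.
#'
#' @slot condition condition label.
#' @slot slopePms,slopePrs fitted slopes (counts/min).
#' @slot t0Pms,t0Prs time-axis intercepts (min).
#' @slot halfTransit `t0Prs - t0Pms` (min).
#' @slot shiftAtMean horizontal displacement between the two fitted lines
#'   evaluated at the mean ordinate (equals `halfTransit` when slopes agree).
#' @slot ci95 numeric(2), bootstrap 95% interval for `halfTransit`.
#' @slot r2Pms,r2Prs coefficients of determination of the two fits.
#' @slot boot bootstrap draws of `halfTransit`.
#' @export
setClass("HalfTransitEstimate", representation(
  condition = "character",
  slopePms = "numeric", slopePrs = "numeric",
  t0Pms = "numeric", t0Prs = "numeric",
  halfTransit = "numeric", shiftAtMean = "numeric",
  ci95 = "numeric", r2Pms = "numeric", r2Prs = "numeric",
  boot = "numeric"
))

setValidity("HalfTransitEstimate", function(object) {
  if (length(object@ci95) == 2L && !any(is.na(object@ci95))) {
    if (object@halfTransit < object@ci95[1] - 1e-12 ||
        object@halfTransit > object@ci95[2] + 1e-12)
      return("ci95 must contain halfTransit")
  }
  TRUE
})
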