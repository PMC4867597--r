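#' @include AllClasses.R annotation.R io.R clip.R
#' @importFrom stats ks.test
NULL

#' Ribosome footprint density per genomic class
#'
#' Footprints are anchored at their P-site (read 5' end plus `psiteOffset`,
#' walked along the spliced transcript) and classified against the
#' region-class partition; densities are anchors per thousand nucleotides of
#' class length. Anchors falling beyond the transcript end are skipped with a
#' message.
#'
#' @param rs a [ReadSet-class] of footprints.
#' @param anno a [TranscriptAnnotation-class].
#' @param psiteOffset P-site offset in nt from the read 5' end (default 12).
#' @return data.frame as in [regionDensity()].
#' @export
footprintDensity <- function(rs, anno, psiteOffset = 12) {
  regionDensity(rs, anno, psiteOffset = psiteOffset)
}

## per-anchor normalized within-region positions for one sample
## returns numeric positions in [0, 1)
.regionPositions <- function(rs, anno, region, geneClass = "all",
                             targets = NULL, psiteOffset = 12) {
  stopifnot(region %in% REGIONS)
  a <- anchorPositions(rs, anno, offset = psiteOffset)$points
  m <- mcols(a)
  keep <- !is.na(m$region) & m$region == region
  if (geneClass != "all") {
    if (is.null(targets)) stop("targets must be supplied for gene-class filters")
    tx <- anno@transcripts
    gene <- tx$gene_id[match(m$transcript_id, tx$transcript_id)]
    keep <- keep & if (geneClass == "target") gene %in% targets
                   else !(gene %in% targets)
  }
  m$regionOffset[keep] / m$regionLength[keep]
}

#' Within-region footprint positions, normalized per transcript
#'
#' Extracts the per-anchor positions (offset / region length, in `[0, 1)`)
#' that the occupancy shift test compares.
#'
#' @inheritParams footprintDensity
#' @param region one of `"utr5"`, `"cds"`, `"utr3"`.
#' @param geneClass `"all"`, `"target"` or `"non-target"`.
#' @param targets character vector of target gene ids (required unless
#'   `geneClass == "all"`).
#' @return Numeric vector of normalized positions.
#' @export
regionPositions <- function(rs, anno, region, geneClass = "all",
                            targets = NULL, psiteOffset = 12) {
  .regionPositions(rs, anno, region, geneClass, targets, psiteOffset)
}

#' Relative ribosome occupancy curve over the binned mRNA axis
#'
#' Computes per-bin raw densities (anchors per kb of aggregate bin extent,
#' as in [metageneProfile()]) over the three regions, then normalizes the
#' whole 3-region curve to sum to 1 so curves are comparable across
#' sequencing depths.
#'
#' @inheritParams regionPositions
#' @param scheme a [BinScheme-class] (20 bins for condition comparisons, 50
#'   for the full metagene view).
#' @param condition condition label stored on the curve (default: the sample
#'   id).
#' @return An [OccupancyCurve-class].
#' @export
occupancyCurve <- function(rs, anno, scheme = BinScheme(20),
                           geneClass = "all", targets = NULL,
                           psiteOffset = 12, condition = sampleId(rs)) {
  stopifnot(is(rs, "ReadSet"))
  use <- rs
  if (geneClass != "all") {
    if (is.null(targets)) stop("targets must be supplied for gene-class filters")
    a <- anchorPositions(rs, anno, offset = 0)$points
    tx <- anno@transcripts
    gene <- tx$gene_id[match(mcols(a)$transcript_id, tx$transcript_id)]
    sel <- if (geneClass == "target") gene %in% targets
           else !is.na(gene) & !(gene %in% targets)
    sel[is.na(sel)] <- FALSE
    use <- ReadSet(sampleId(rs), reads(rs)[sel])
  }
  mp <- metageneProfile(use, anno, scheme = scheme, psiteOffset = psiteOffset)
  if (mp@nFeatures == 0L)
    stop(sprintf("no footprints left after filtering (geneClass = '%s')",
                 geneClass))
  raw <- binDensity(mp)
  raw[is.na(raw)] <- 0
  new("OccupancyCurve", condition = condition, geneClass = geneClass,
      scheme = scheme, density = raw / sum(raw),
      nFootprints = mp@nFeatures)
}

#' Two-sample Kolmogorov-Smirnov test for an occupancy shift
#'
#' Compares per-anchor normalized within-region positions between two sides
#' with the two-sample KS test (asymptotic p). The test runs on anchors, not
#' on binned curves, so the sample size is well defined. Both sides must have
#' at least `minN` anchors.
#'
#' @param posA,posB numeric vectors of normalized positions in `[0, 1)` (see
#'   [regionPositions()]).
#' @param region region label recorded on the result.
#' @param labels character(2) naming the two sides.
#' @param minN minimum anchors per side (default 30, for asymptotic p
#'   validity).
#' @return A [ShiftTestResult-class].
#' @export
shiftTest <- function(posA, posB, region = "cds", labels = c("A", "B"),
                      minN = 30) {
  if (length(posA) < minN || length(posB) < minN)
    stop(sprintf("need >= %d anchors per side (got %d and %d)", minN,
                 length(posA), length(posB)))
  kt <- suppressWarnings(ks.test(posA, posB, exact = FALSE))
  new("ShiftTestResult", region = region, comparison = labels,
      D = unname(kt$statistic), p = max(unname(kt$p.value), .Machine$double.xmin),
      nA = length(posA), nB = length(posB))
}

#' Cross-condition ribosome occupancy comparison
#'
#' For every pair of conditions and each gene class (target, non-target),
#' runs the KS shift test on CDS and 5'-UTR anchor positions, and reports the
#' per-condition 5'-UTR/CDS density ratio (anchors per nt of 5'-UTR divided
#' by anchors per nt of CDS, over the genes of the class).
#'
#' @param readsByCondition named list of [ReadSet-class] objects, one per
#'   condition (>= 2).
#' @param anno a [TranscriptAnnotation-class].
#' @param targets character vector of target gene ids.
#' @param psiteOffset P-site offset (default 12).
#' @param regions regions to shift-test (default CDS and 5'-UTR).
#' @param minN minimum anchors per side for the KS test.
#' @return list with `tests` (data.frame: conditionA, conditionB, geneClass,
#'   region, D, p, nA, nB) and `ratios` (data.frame: condition, geneClass,
#'   utr5_density, cds_density, utr5_cds_ratio).
#' @export
compareConditions <- function(readsByCondition, anno, targets,
                              psiteOffset = 12, regions = c("cds", "utr5"),
                              minN = 30) {
  conds <- names(readsByCondition)
  if (is.null(conds) || any(conds == ""))
    stop("readsByCondition must be a named list")
  if (length(conds) < 2L) stop("need at least two conditions")
  tx <- anno@transcripts
  classes <- c("target", "non-target")

  ## anchor each condition once; all class/region position vectors and the
  ## density ratios are derived from the same cached anchors
  anchors <- lapply(readsByCondition, function(rs)
    S4Vectors::mcols(anchorPositions(rs, anno, offset = psiteOffset)$points))
  posCache <- list()
  for (cd in conds) {
    m <- anchors[[cd]]
    gene <- tx$gene_id[match(m$transcript_id, tx$transcript_id)]
    isT <- !is.na(gene) & gene %in% targets
    for (gc in classes) for (r in regions) {
      keep <- !is.na(m$region) & m$region == r &
        (if (gc == "target") isT else !is.na(gene) & !isT)
      posCache[[paste(cd, gc, r)]] <- m$regionOffset[keep] / m$regionLength[keep]
    }
  }

  tests <- list()
  for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
    for (gc in classes) for (r in regions) {
      st <- shiftTest(posCache[[paste(conds[i], gc, r)]],
                      posCache[[paste(conds[j], gc, r)]],
                      region = r, labels = c(conds[i], conds[j]), minN = minN)
      tests[[length(tests) + 1L]] <- data.frame(
        conditionA = conds[i], conditionB = conds[j], geneClass = gc,
        region = r, D = st@D, p = st@p, nA = st@nA, nB = st@nB)
    }
  }

  ratios <- list()
  coding <- tx[tx$cds_len > 0, , drop = FALSE]
  for (cd in conds) {
    m <- anchors[[cd]]
    gene <- tx$gene_id[match(m$transcript_id, tx$transcript_id)]
    for (gc in classes) {
      inClass <- if (gc == "target") gene %in% targets
                 else !is.na(gene) & !(gene %in% targets)
      geneSel <- if (gc == "target") coding$gene_id %in% targets
                 else !(coding$gene_id %in% targets)
      lenU5 <- sum(coding$utr5_len[geneSel])
      lenCds <- sum(coding$cds_len[geneSel])
      dU5 <- sum(inClass & !is.na(m$region) & m$region == "utr5") / lenU5
      dCds <- sum(inClass & !is.na(m$region) & m$region == "cds") / lenCds
      ratios[[length(ratios) + 1L]] <- data.frame(
        condition = cd, geneClass = gc, utr5_density = dU5,
        cds_density = dCds,
        utr5_cds_ratio = if (dCds > 0) dU5 / dCds else NA_real_)
    }
  }
  list(tests = do.call(rbind, tests), ratios = do.call(rbind, ratios))
}
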