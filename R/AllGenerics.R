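#' @include AllClasses.R
NULL

#' @export
setGeneric("transcripts", function(object, ...) standardGeneric("transcripts"))
#' @export
setGeneric("classMap", function(object) standardGeneric("classMap"))
#' @export
setGeneric("classLengths", function(object) standardGeneric("classLengths"))
#' @export
setGeneric("reads", function(object) standardGeneric("reads"))
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @export
setGeneric("totalMapped", function(object) standardGeneric("totalMapped"))
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @export
setGeneric("peakParams", function(object) standardGeneric("peakParams"))
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))
#' @export
setGeneric("binLengths", function(object) standardGeneric("binLengths"))
#' @export
setGeneric("binDensity", function(object) standardGeneric("binDensity"))
#' @export
setGeneric("halfTransit", function(object) standardGeneric("halfTransit"))
#' @export
setGeneric("ci95", function(object) standardGeneric("ci95"))

#' Accessors for riboclip classes
#'
#' Standard accessors for the package's S4 containers; use these rather than
#' direct slot access.
#'
#' @param object a riboclip S4 object.
#' @param ... unused.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases transcripts classMap classLengths reads sampleId totalMapped
#'   peaks peakParams nBins binCounts binLengths binDensity halfTransit ci95
NULL

#' @rdname accessors
setMethod("transcripts", "TranscriptAnnotation", function(object, ...) object@transcripts)
#' @rdname accessors
setMethod("classMap", "TranscriptAnnotation", function(object) object@classMap)
#' @rdname accessors
setMethod("classLengths", "TranscriptAnnotation", function(object) object@classLengths)
#' @rdname accessors
setMethod("reads", "ReadSet", function(object) object@reads)
#' @rdname accessors
setMethod("sampleId", "ReadSet", function(object) object@sampleId)
#' @rdname accessors
setMethod("totalMapped", "ReadSet", function(object) object@totalMapped)
#' @rdname accessors
setMethod("peaks", "PeakCall", function(object) object@peaks)
#' @rdname accessors
setMethod("peakParams", "PeakCall", function(object) object@params)
#' @rdname accessors
setMethod("nBins", "BinScheme", function(object) object@nBins)
#' @rdname accessors
setMethod("nBins", "MetageneProfile", function(object) object@scheme@nBins)
#' @rdname accessors
setMethod("nBins", "OccupancyCurve", function(object) object@scheme@nBins)
#' @rdname accessors
setMethod("binCounts", "MetageneProfile", function(object) object@counts)
#' @rdname accessors
setMethod("binLengths", "MetageneProfile", function(object) object@binLengths)
#' @rdname accessors
setMethod("binDensity", "MetageneProfile", function(object) object@density)
#' @rdname accessors
setMethod("binDensity", "OccupancyCurve", function(object) object@density)
#' @rdname accessors
setMethod("halfTransit", "HalfTransitEstimate", function(object) object@halfTransit)
#' @rdname accessors
setMethod("ci95", "HalfTransitEstimate", function(object) object@ci95)

setMethod("show", "BinScheme", function(object) {
  cat("BinScheme:", object@nBins, "bins per region\n")
})

setMethod("show", "TranscriptAnnotation", function(object) {
  tx <- object@transcripts
  cat("TranscriptAnnotation with", nrow(tx), "transcripts (",
      length(unique(tx$gene_id)), "genes )\n")
  if (nrow(tx)) {
    cat("  gene types:",
        paste(sprintf("%s=%d", names(table(tx$gene_type)), table(tx$gene_type)),
              collapse = ", "), "\n")
  }
  cl <- object@classLengths
  cat("  class lengths (nt):",
      paste(sprintf("%s=%g", REGION_LABELS[names(cl)], cl), collapse = ", "), "\n")
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet '", object@sampleId, "': ", object@totalMapped,
      " mapped reads\n", sep = "")
})

setMethod("show", "PeakCall", function(object) {
  cat("PeakCall:", length(object@peaks), "merged peaks (",
      object@nTested, "windows tested )\n")
  p <- object@params
  cat(sprintf("  window=%d step=%d pseudocount=%g fdr=%g minCount=%d\n",
              p$window, p$step, p$pseudocount, p$fdr, p$minCount))
})

setMethod("show", "MetageneProfile", function(object) {
  cat("MetageneProfile:", object@nFeatures, "features over",
      object@scheme@nBins, "bins/region\n")
  cat("  genes contributing:",
      paste(sprintf("%s=%d", REGION_LABELS[REGIONS], object@nGenes[REGIONS]),
            collapse = ", "), "\n")
})

setMethod("show", "OccupancyCurve", function(object) {
  cat(sprintf("OccupancyCurve [%s / %s]: %d footprints, %d bins/region\n",
              object@condition, object@geneClass, object@nFootprints,
              object@scheme@nBins))
})

setMethod("show", "ShiftTestResult", function(object) {
  cat(sprintf("ShiftTestResult [%s] %s vs %s: D=%.4f, p=%.3g (n=%d/%d)\n",
              REGION_LABELS[object@region], object@comparison[1],
              object@comparison[2], object@D, object@p,
              as.integer(object@nA), as.integer(object@nB)))
})

setMethod("show", "HalfTransitEstimate", function(object) {
  cat(sprintf("HalfTransitEstimate [%s]: 1/2 tau = %.3f min", object@condition,
              object@halfTransit))
  if (!any(is.na(object@ci95)))
    cat(sprintf(" (95%% CI %.3f-%.3f)", object@ci95[1], object@ci95[2]))
  cat(sprintf("\n  slopes PMS=%.3g PRS=%.3g; R2 PMS=%.3f PRS=%.3f\n",
              object@slopePms, object@slopePrs, object@r2Pms, object@r2Prs))
})
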