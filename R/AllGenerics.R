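#' Accessors for fNIRS containers
#'
#' `samplingRate()` returns the sampling rate in Hz, `taskOnsets()` the
#' task-onset times in seconds, `participantID()` and `lesionSide()` the
#' participant metadata, `pathType()`, `hemisphere()` and `pairIndex()` the
#' per-channel montage annotation, and `stageLog()` the list of processing
#' stages applied so far.
#'
#' @param x a [FnirsRecording], [HemoSeries] or [CleanSeries] (or, where
#'   noted, a [LateralityRecord]).
#' @return see individual descriptions.
#' @name fnirs-accessors
#' @aliases samplingRate taskOnsets participantID lesionSide pathType
#'   hemisphere pairIndex stageLog lateralityValues
NULL

#' @rdname fnirs-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname fnirs-accessors
#' @export
setGeneric("taskOnsets", function(x) standardGeneric("taskOnsets"))
#' @rdname fnirs-accessors
#' @export
setGeneric("participantID", function(x) standardGeneric("participantID"))
#' @rdname fnirs-accessors
#' @export
setGeneric("lesionSide", function(x) standardGeneric("lesionSide"))
#' @rdname fnirs-accessors
#' @export
setGeneric("pathType", function(x) standardGeneric("pathType"))
#' @rdname fnirs-accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))
#' @rdname fnirs-accessors
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))
#' @rdname fnirs-accessors
#' @export
setGeneric("stageLog", function(x) standardGeneric("stageLog"))
#' @rdname fnirs-accessors
#' @export
setGeneric("lateralityValues", function(x) standardGeneric("lateralityValues"))

.se_classes <- c("FnirsRecording", "HemoSeries", "CleanSeries")

for (.cl in .se_classes) {
  setMethod("samplingRate", .cl, function(x) metadata(x)$fs)
  setMethod("taskOnsets", .cl, function(x) metadata(x)$events$onset)
  setMethod("participantID", .cl, function(x) metadata(x)$participant)
  setMethod("lesionSide", .cl, function(x) metadata(x)$lesionSide)
  setMethod("pathType", .cl, function(x) rowData(x)$pathType)
  setMethod("hemisphere", .cl, function(x) rowData(x)$hemisphere)
  setMethod("pairIndex", .cl, function(x) rowData(x)$pairIndex)
  setMethod("stageLog", .cl, function(x) metadata(x)$stageLog)
}

setMethod("participantID", "LateralityRecord", function(x) x@participant)
setMethod("lesionSide", "LateralityRecord", function(x) x@lesionSide)

#' @rdname fnirs-accessors
#' @export
setMethod("lateralityValues", "LateralityRecord", function(x) x@values)

setMethod("show", "FnirsRecording", function(object) {
  cat("FnirsRecording:", sum(pathType(object) == "long"), "long +",
      sum(pathType(object) == "short"), "short channels,",
      ncol(object), "samples @", samplingRate(object), "Hz\n")
  cat("  participant:", participantID(object),
      "| lesion side:", lesionSide(object),
      "|", length(taskOnsets(object)), "task onsets\n")
})

setMethod("show", "CleanSeries", function(object) {
  cat("CleanSeries:", nrow(object), "long channels,", ncol(object),
      "samples @", samplingRate(object), "Hz;",
      length(stageLog(object)), "stages applied\n")
})

setMethod("show", "LateralityRecord", function(object) {
  v <- object@values
  cat("LateralityRecord for", object@participant,
      "(lesion:", paste0(object@lesionSide, "):"),
      nrow(v), "trials x 8 pairs; grand mean",
      signif(mean(v, na.rm = TRUE), 3), "\n")
})

setMethod("show", "SemPosterior", function(object) {
  cat("SemPosterior:", nrow(object@draws), "draws (",
      length(unique(object@chain)), "chains ) x",
      ncol(object@draws), "parameters\n")
})

setMethod("show", "SemDiagnostics", function(object) {
  cat("SemDiagnostics:", if (object@pass) "PASS" else "FAIL",
      "| divergences:", object@nDivergent,
      "| max Rhat:", signif(max(object@table$rhat, na.rm = TRUE), 4),
      "| min tail-ESS:", round(min(object@table$tailESS, na.rm = TRUE)), "\n")
})
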