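#' Container classes for fNIRS laterality analysis
#'
#' `FnirsRecording` holds raw two-wavelength optical intensities, one row per
#' measurement channel and one column per sample, as a
#' [SummarizedExperiment::SummarizedExperiment] with assays `"wl1"` and
#' `"wl2"` (the per-channel wavelength in nm lives in `rowData`). Long-path
#' channels (30 mm source-detector separation, 745/850 nm) carry cerebral
#' signal; short-path channels (8 mm, 735/850 nm) are scalp/systemic noise
#' references. `HemoSeries` holds per-channel relative oxy- and
#' deoxyhemoglobin (`"HbO"`, `"Hb"` assays) after modified Beer-Lambert
#' conversion, and `CleanSeries` the denoised oxyhemoglobin (`"clean"`
#' assay) restricted to long-path channels.
#'
#' Shared metadata (sampling rate, task-onset events, participant id, lesion
#' side, stage log) lives in `metadata()` and is carried through the
#' pipeline.
#'
#' @aliases FnirsRecording-class HemoSeries-class CleanSeries-class
#' @name fnirs-classes
NULL

.fnirsValidity <- function(object) {
  msg <- character()
  md <- metadata(object)
  if (is.null(md$fs) || !is.numeric(md$fs) || md$fs <= 0)
    msg <- c(msg, "metadata 'fs' must be a positive sampling rate in Hz")
  rd <- rowData(object)
  need <- c("channel", "pathType", "hemisphere", "pairIndex")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("rowData is missing:", paste(miss, collapse = ", ")))
  if (!is.null(md$events)) {
    ev <- md$events
    if (!is.data.frame(ev) || !all(c("onset", "duration") %in% names(ev)))
      msg <- c(msg, "metadata 'events' must have columns onset, duration")
    else if (ncol(object) > 0 && any(ev$onset < 0 | ev$onset * md$fs > ncol(object)))
      msg <- c(msg, "event onsets fall outside the recording")
  }
  if (length(msg)) msg else TRUE
}

#' @rdname fnirs-classes
#' @export
setClass("FnirsRecording", contains = "SummarizedExperiment")

setValidity("FnirsRecording", function(object) {
  msg <- .fnirsValidity(object)
  out <- if (isTRUE(msg)) character() else msg
  if (!all(c("wl1", "wl2") %in% assayNames(object)))
    out <- c(out, "assays 'wl1' and 'wl2' are required")
  else if (any(vapply(assays(object), function(a) any(!is.finite(a)) || any(a <= 0),
                      logical(1))))
    out <- c(out, "intensities must be finite and strictly positive")
  rd <- rowData(object)
  if ("pathType" %in% colnames(rd) && "shortRef" %in% colnames(rd)) {
    long <- rd$pathType == "long"
    shorts <- rd$channel[rd$pathType == "short"]
    if (any(long) && !all(rd$shortRef[long] %in% shorts))
      out <- c(out, "every long channel must reference an existing short channel")
  }
  if (length(out)) out else TRUE
})

#' @rdname fnirs-classes
#' @export
setClass("HemoSeries", contains = "SummarizedExperiment")

setValidity("HemoSeries", function(object) {
  msg <- .fnirsValidity(object)
  out <- if (isTRUE(msg)) character() else msg
  if (!all(c("HbO", "Hb") %in% assayNames(object)))
    out <- c(out, "assays 'HbO' and 'Hb' are required")
  else if (any(vapply(assays(object), function(a) any(!is.finite(a)), logical(1))))
    out <- c(out, "hemoglobin series must be finite")
  if (length(out)) out else TRUE
})

#' @rdname fnirs-classes
#' @export
setClass("CleanSeries", contains = "SummarizedExperiment")

setValidity("CleanSeries", function(object) {
  msg <- .fnirsValidity(object)
  out <- if (isTRUE(msg)) character() else msg
  if (!("clean" %in% assayNames(object)))
    out <- c(out, "assay 'clean' is required")
  if (length(out)) out else TRUE
})

#' Per-trial homotopic laterality values
#'
#' One participant's M1-LAT values: for each trial and each of the 8
#' homotopic location pairs, the contralesional-minus-ipsilesional
#' difference of task-window oxyhemoglobin slopes (concentration units per
#' second). The sign convention is fixed by `lesionSide`: ipsilesional is
#' the hemisphere named there.
#'
#' @slot participant single participant identifier.
#' @slot lesionSide `"left"` or `"right"`.
#' @slot values numeric matrix, trials x 8 pairs; columns ordered by
#'   medial-to-lateral pair index. Missing pair members yield `NA`.
#' @export
setClass("LateralityRecord",
  representation(participant = "character", lesionSide = "character",
                 values = "matrix"))

setValidity("LateralityRecord", function(object) {
  msg <- character()
  if (length(object@participant) != 1L) msg <- c(msg, "one participant per record")
  if (!object@lesionSide %in% c("left", "right"))
    msg <- c(msg, "lesionSide must be 'left' or 'right'")
  if (ncol(object@values) != 8L) msg <- c(msg, "exactly 8 homotopic pair columns")
  if (length(msg)) msg else TRUE
})

#' Posterior draws from the latent-trait SEM
#'
#' @slot draws numeric matrix, one row per retained draw (all chains
#'   stacked), one column per parameter.
#' @slot chain integer chain index per row.
#' @slot iteration integer within-chain iteration per row.
#' @slot info list of sampler metadata: `sampler`, `seed`, `chains`,
#'   `warmup`, `nDraws`, `nDivergent` (0 for the JAGS backend, which has no
#'   divergence concept), `monitors`, `dims`.
#' @export
setClass("SemPosterior",
  representation(draws = "matrix", chain = "integer", iteration = "integer",
                 info = "list"))

setValidity("SemPosterior", function(object) {
  msg <- character()
  if (nrow(object@draws) != length(object@chain) ||
      nrow(object@draws) != length(object@iteration))
    msg <- c(msg, "chain/iteration must index rows of draws")
  if (is.null(colnames(object@draws))) msg <- c(msg, "draws must have parameter names")
  if (length(msg)) msg else TRUE
})

#' MCMC convergence report
#'
#' Pass requires zero divergent transitions, max rank-normalized split-Rhat
#' below `rhatLimit`, and min tail effective sample size at or above
#' `essFloor`.
#'
#' @slot table per-parameter data.frame with columns `param`, `rhat`,
#'   `tailESS`.
#' @slot nDivergent integer divergence count copied from sampler metadata.
#' @slot rhatLimit,essFloor the thresholds applied.
#' @slot pass overall pass flag.
#' @export
setClass("SemDiagnostics",
  representation(table = "data.frame", nDivergent = "integer",
                 rhatLimit = "numeric", essFloor = "numeric", pass = "logical"))
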