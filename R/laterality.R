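#' Extract per-trial task-window epochs
#'
#' Cuts one epoch per (trial, long channel) from the clean series: the
#' half-open window `[onset, onset + task_s)`, i.e. `round(task_s * fs)`
#' samples starting at the onset sample. After the pipeline's per-trial
#' baseline correction, the first sample of every epoch is 0.
#'
#' @param clean a [CleanSeries].
#' @param task_s task-window length (s); defaults to the recorded event
#'   duration.
#' @return array `trials x channels x samples` with attributes `fs` and
#'   `onsets`.
#' @export
epochTrials <- function(clean, task_s = NULL) {
  stopifnot(is(clean, "CleanSeries"))
  fs <- samplingRate(clean)
  ev <- metadata(clean)$events
  if (is.null(task_s)) task_s <- ev$duration[1]
  onsets <- ev$onset
  nWin <- round(task_s * fs)
  if (length(onsets) > 1 && any(diff(onsets) * fs < nWin))
    stop("task windows overlap")
  starts <- round(onsets * fs) + 1L
  if (any(starts + nWin - 1L > ncol(clean)))
    stop("an onset plus the task window falls beyond the recording end")
  x <- assay(clean, "clean")
  out <- array(NA_real_,
               dim = c(length(onsets), nrow(x), nWin),
               dimnames = list(NULL, rownames(x), NULL))
  for (k in seq_along(onsets))
    out[k, , ] <- x[, starts[k]:(starts[k] + nWin - 1L)]
  attr(out, "fs") <- fs
  attr(out, "onsets") <- onsets
  out
}

#' Task-window slope
#'
#' Ordinary least-squares slope of the oxyhemoglobin values against time
#' (seconds, origin at onset) over the task window. With the task timing
#' producing a near-monotone rise, this slope summarizes task-related
#' activation at one location on one trial.
#'
#' @param epoch numeric vector (one epoch) or the epoch array from
#'   [epochTrials()].
#' @param fs sampling rate (Hz); taken from the array attribute when
#'   present.
#' @return a single slope, or a `trials x channels` matrix of slopes
#'   (concentration units per second).
#' @export
taskSlope <- function(epoch, fs = attr(epoch, "fs")) {
  slope1 <- function(x) {
    tt <- (seq_along(x) - 1) / fs
    tc <- tt - mean(tt)
    sum(tc * (x - mean(x))) / sum(tc^2)
  }
  if (is.null(dim(epoch))) {
    if (length(epoch) < 2) stop("need at least 2 samples")
    return(slope1(epoch))
  }
  apply(epoch, c(1, 2), slope1)
}

#' Per-trial homotopic laterality (M1-LAT)
#'
#' For each trial and each of the 8 homotopic location pairs, the
#' contralesional slope minus the ipsilesional slope, where the
#' ipsilesional hemisphere is the one named by `lesion_side`. Swapping the
#' lesion side negates every value. A missing pair member yields `NA`,
#' never 0.
#'
#' @param slopes `trials x channels` slope matrix (16 long channels,
#'   columns named by channel id) from [taskSlope()].
#' @param montage the montage, see [m1Montage()].
#' @param lesion_side `"left"` or `"right"`.
#' @param participant participant id stored in the record.
#' @return a [LateralityRecord].
#' @export
m1Laterality <- function(slopes, montage = m1Montage(), lesion_side,
                         participant = "P01") {
  stopifnot(lesion_side %in% c("left", "right"))
  pairs <- homotopicPairs(montage)
  contraSide <- setdiff(c("left", "right"), lesion_side)
  vals <- matrix(NA_real_, nrow(slopes), 8,
                 dimnames = list(NULL, paste0("pair_", pairs$pairIndex)))
  for (r in seq_len(nrow(pairs))) {
    contraCh <- if (contraSide == "left") pairs$left[r] else pairs$right[r]
    ipsiCh <- if (lesion_side == "left") pairs$left[r] else pairs$right[r]
    if (contraCh %in% colnames(slopes) && ipsiCh %in% colnames(slopes))
      vals[, r] <- slopes[, contraCh] - slopes[, ipsiCh]
  }
  new("LateralityRecord", participant = participant,
      lesionSide = lesion_side, values = vals)
}

#' Laterality records as a long table
#'
#' @param records a [LateralityRecord] or list of them.
#' @return data.frame with columns `participant_id`, `lesion_side`,
#'   `trial`, `pair_index`, `m1lat`.
#' @export
lateralityTable <- function(records) {
  if (is(records, "LateralityRecord")) records <- list(records)
  do.call(rbind, lapply(records, function(r) {
    v <- r@values
    data.frame(participant_id = r@participant,
               lesion_side = r@lesionSide,
               trial = rep(seq_len(nrow(v)), 8),
               pair_index = rep(1:8, each = nrow(v)),
               m1lat = as.vector(v))
  }))
}
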