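#' Canonical double-gamma hemodynamic response
#'
#' Impulse response used by the synthetic-data generator: a positive gamma
#' bump with configurable peak time minus a scaled later undershoot, peak
#' amplitude normalized to 1. Each gamma component is parameterized so that
#' its mode sits exactly at its `peak`/`undershoot` argument,
#' \eqn{g(t; p, b) = (t/p)^{p/b} e^{(p - t)/b}}.
#'
#' @param t time since stimulus onset, seconds; must be non-negative.
#' @param peak mode of the positive component (s).
#' @param undershoot mode of the undershoot component (s).
#' @param dispersion width parameter of both components (s).
#' @param ratio amplitude of the undershoot relative to the main bump.
#' @return unitless amplitude, same length as `t`, with `max == 1` attained
#'   near `peak` and `h(0) == 0`.
#' @examples
#' canonicalHrf(c(0, 6, 60))
#' @export
canonicalHrf <- function(t, peak = 6, undershoot = 16, dispersion = 0.9,
                         ratio = 0.35) {
  if (any(t < 0)) stop("canonicalHrf is defined for t >= 0 only")
  h <- .hrfRaw(t, peak, undershoot, dispersion, ratio)
  h / .hrfPeakValue(peak, undershoot, dispersion, ratio)
}

.gammaBump <- function(t, p, b) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp((p / b) * log(t[pos] / p) + (p - t[pos]) / b)
  out
}

.hrfRaw <- function(t, peak, undershoot, dispersion, ratio) {
  .gammaBump(t, peak, dispersion) - ratio * .gammaBump(t, undershoot, dispersion)
}

.hrfPeakValue <- function(peak, undershoot, dispersion, ratio) {
  opt <- stats::optimize(function(t) .hrfRaw(t, peak, undershoot, dispersion, ratio),
                         interval = c(0, undershoot), maximum = TRUE,
                         tol = 1e-10)
  opt$objective
}

# OLS slope (per second) of the unit-peak task response over the task
# window; used to convert target slopes into response gains.
.unitResponseSlope <- function(fs, task_s, hrfArgs = list()) {
  r <- .taskResponse(fs, task_s, ceiling(task_s * fs) + 1L, hrfArgs)
  n <- round(task_s * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- r[seq_len(n)]
  sum((tt - mean(tt)) * (x - mean(x))) / sum((tt - mean(tt))^2)
}

# boxcar (task_s) convolved with the canonical HRF, sampled at fs,
# normalized to unit peak; length n samples from task onset
.taskResponse <- function(fs, task_s, n, hrfArgs = list()) {
  tmax <- (n - 1) / fs + 40            # let the response decay
  tg <- seq(0, tmax, by = 1 / fs)
  h <- do.call(canonicalHrf, c(list(t = tg), hrfArgs))
  box <- as.numeric(tg < task_s)
  r <- stats::convolve(box, rev(h), type = "open")[seq_along(tg)] / fs
  r <- r / max(r)
  r[seq_len(n)]
}
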