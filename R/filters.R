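#' Nominal physiological frequency bands
#'
#' Cardiac pulse (0.5-1.5 Hz), respiration (0.15-0.3 Hz), Mayer wave
#' (0.05-0.15 Hz) and the band containing the hemodynamic (BOLD) response
#' (0.01-0.1 Hz).
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @export
defaultBands <- function() {
  data.frame(name = c("cardiac", "respiration", "mayer", "bold"),
             low = c(0.5, 0.15, 0.05, 0.01),
             high = c(1.5, 0.30, 0.15, 0.10))
}

.bandRow <- function(band) {
  if (is.character(band)) {
    bands <- defaultBands()
    band <- bands[bands$name == band, ]
    if (nrow(band) != 1) stop("unknown band name")
  }
  as.list(band)
}

# direct-form II transposed IIR filter with optional initial conditions,
# matching scipy.signal.lfilter
.iirFilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z[1]
    if (nf > 2)
      for (k in seq_len(nf - 2)) z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi
    z[nf - 1] <- b[nf] * x[i] - a[nf] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial conditions of an IIR filter for a unit step,
# matching scipy.signal.lfilter_zi
.lfilterZi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  n <- nf - 1
  A <- rbind(-a[2:nf], cbind(diag(1, n - 1), rep(0, n - 1)))[seq_len(n), , drop = FALSE]
  B <- b[2:nf] - a[2:nf] * b[1]
  solve(diag(1, n) - t(A), B)
}

# zero-phase filtering, forward-backward with steady-state edge init
# (the scipy filtfilt padlen=0 convention)
.filtfiltZi <- function(b, a, x) {
  zi <- .lfilterZi(b, a)
  y <- .iirFilter(b, a, x, zi * x[1])
  y <- rev(y)
  y <- .iirFilter(b, a, y, zi * y[1])
  rev(y)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward Butterworth band-pass with odd-reflection edge padding,
#' so in-band components keep their amplitude and phase and slope
#' estimates are not skewed by group delay.
#'
#' @param x numeric time series.
#' @param band a band name from [defaultBands()] or a list/row with
#'   `name`, `low`, `high` (Hz).
#' @param fs sampling rate (Hz).
#' @param order Butterworth section order (applied twice by the
#'   forward-backward pass).
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, band, fs, order = 2) {
  band <- .bandRow(band)
  ny <- fs / 2
  if (band$low <= 0 || band$high >= ny)
    stop(sprintf("band '%s' (%.3g-%.3g Hz) is invalid for fs = %g Hz",
                 band$name, band$low, band$high, fs))
  n <- length(x)
  if (n < 10) stop("signal too short to filter")
  bf <- signal::butter(order, c(band$low, band$high) / ny, type = "pass")
  npad <- min(n - 1L, ceiling(3 * fs / band$low))
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- .filtfiltZi(bf$b, bf$a, xp)
  y[(npad + 1):(npad + n)]
}

#' Temporal derivative distribution repair
#'
#' Motion-artifact correction: the signal is split into a low-frequency
#' part (zero-phase Butterworth low-pass at 0.5 Hz) and a high-frequency
#' remainder; the temporal derivative of the low-frequency part is
#' iteratively re-weighted with Tukey's biweight around a robust mean until
#' convergence, outlying derivatives (motion spikes and steps) are shrunk
#' toward zero, and the repaired derivative is re-integrated and recombined
#' with the untouched high-frequency part. Mean level is preserved.
#'
#' Signals whose derivative has zero robust spread (constant or noise-free
#' segments dominating) are returned unchanged.
#'
#' @param x numeric time series (any units; typically raw intensity).
#' @param fs sampling rate (Hz).
#' @return repaired series, same length as `x`.
#' @references Fishburn et al. (2019), NeuroImage 184:171-179.
#' @export
tddr <- function(x, fs) {
  if (length(x) < 3) stop("tddr needs at least 3 samples")
  if (any(!is.finite(x))) stop("tddr requires finite input")
  m <- mean(x)
  xc <- x - m
  fc <- 0.5 * 2 / fs
  if (fc < 1) {
    bf <- signal::butter(3, fc, type = "low")
    low <- .filtfiltZi(bf$b, bf$a, xc)
  } else {
    low <- xc
  }
  high <- xc - low
  deriv <- diff(low)
  tune <- 4.685
  eps <- sqrt(.Machine$double.eps)
  w <- rep(1, length(deriv))
  mu <- Inf
  for (iter in seq_len(50)) {
    mu0 <- mu
    mu <- sum(w * deriv) / sum(w)
    dev <- abs(deriv - mu)
    sigma <- 1.4826 * median(dev)
    if (sigma == 0) return(x)        # nothing to repair
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (r < 1))^2
    if (abs(mu - mu0) < eps * max(abs(mu), abs(mu0))) break
  }
  repaired <- cumsum(c(0, w * (deriv - mu)))
  repaired <- repaired - mean(repaired)
  repaired + high + m
}
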