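#' Hemoglobin extinction coefficients
#'
#' Molar extinction coefficients (1/(mM cm)) of oxy- and deoxyhemoglobin at
#' the headband's three wavelengths. Absolute calibration is immaterial for
#' laterality, which is a within-recording difference; the coefficients set
#' the relative mixing of the two chromophores.
#'
#' @return matrix with rownames `"735"`, `"745"`, `"850"` and columns
#'   `HbO`, `Hb`.
#' @export
extinctionCoefficients <- function() {
  m <- rbind("735" = c(HbO = 0.50, Hb = 1.25),
             "745" = c(HbO = 0.53, Hb = 1.15),
             "850" = c(HbO = 1.06, Hb = 0.69))
  m
}

#' Modified Beer-Lambert conversion
#'
#' Converts a channel's two-wavelength intensity series to relative oxy-
#' and deoxyhemoglobin. Optical density is `-log(I / I0)` with `I0` the
#' temporal mean intensity; concentrations solve
#' `E %*% c(dHbO, dHb) = dOD / (distance * dpf)` per wavelength.
#'
#' @param intensities numeric matrix, 2 rows (wavelengths) x time, strictly
#'   positive.
#' @param distance source-detector separation (cm).
#' @param dpf length-2 differential pathlength factors.
#' @param extinction 2 x 2 matrix, rows matching the wavelength rows of
#'   `intensities`, columns `HbO`, `Hb`.
#' @return list with numeric vectors `HbO` and `Hb` (uM, with the
#'   extinction table in per-(mM cm) units).
#' @export
mbll <- function(intensities, distance, dpf, extinction) {
  if (any(intensities <= 0)) stop("intensities must be strictly positive")
  if (abs(det(extinction)) < 1e-12)
    stop("extinction matrix is singular for this wavelength pair")
  I0 <- rowMeans(intensities)
  od <- -log(intensities / I0)
  rhs <- od / (distance * dpf)
  conc <- 1e3 * solve(extinction, rhs)
  list(HbO = conc[1, ], Hb = conc[2, ])
}

#' Inter-channel delay estimation within a frequency band
#'
#' Band-passes each channel, then finds, per channel, the lag (seconds)
#' maximizing the cross-correlation with the reference -- the across-channel
#' mean of the band-passed signals -- within `+/-maxLag`, refined to
#' sub-sample resolution by parabolic interpolation of the correlation
#' peak. Flat channels get delay 0 and are flagged.
#'
#' @param x numeric matrix, channels x time (typically 850 nm intensity).
#' @param band band name or definition (see [bandpass()]).
#' @param fs sampling rate (Hz).
#' @param maxLag search half-window (s); default one period of the band's
#'   centre frequency, capped at 2 s.
#' @param refRows optional row indices whose band-passed mean forms the
#'   reference (default: all rows).
#' @return named numeric vector of delays (s), one per channel (positive =
#'   channel lags the reference), with attribute `"flat"` flagging
#'   channels that could not be estimated.
#' @export
estimateDelays <- function(x, band, fs, maxLag = NULL, refRows = NULL) {
  band <- .bandRow(band)
  if (is.null(dim(x)) || nrow(x) < 2) stop("need at least 2 channels")
  if (is.null(maxLag)) maxLag <- min(2, 2 / (band$low + band$high))
  L <- max(1L, round(maxLag * fs))
  filt <- t(apply(x, 1, bandpass, band = band, fs = fs))
  if (is.null(refRows)) refRows <- seq_len(nrow(filt))
  ref <- colMeans(filt[refRows, , drop = FALSE])
  nCh <- nrow(filt)
  delays <- numeric(nCh)
  flat <- logical(nCh)
  lags <- -L:L
  if (sd(ref) == 0) {
    warning("flat reference: all delays set to 0")
    names(delays) <- rownames(x)
    attr(delays, "flat") <- rep(TRUE, nCh)
    return(delays)
  }
  for (ch in seq_len(nCh)) {
    s <- filt[ch, ]
    if (sd(s) < .Machine$double.eps^0.5 * max(1, abs(mean(x[ch, ])))) {
      flat[ch] <- TRUE
      next
    }
    cc <- vapply(lags, function(l) .laggedCor(s, ref, l), numeric(1))
    k <- which.max(cc)
    lag <- lags[k]
    if (k > 1 && k < length(lags)) {
      y1 <- cc[k - 1]; y2 <- cc[k]; y3 <- cc[k + 1]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    delays[ch] <- lag / fs
  }
  if (any(flat)) warning(sum(flat), " flat channel(s): delay set to 0")
  names(delays) <- rownames(x)
  attr(delays, "flat") <- flat
  delays
}

# correlation between s shifted by `lag` samples and ref (overlap only)
.laggedCor <- function(s, ref, lag) {
  n <- length(s)
  if (lag >= 0) {
    a <- s[(1 + lag):n]; b <- ref[1:(n - lag)]
  } else {
    a <- s[1:(n + lag)]; b <- ref[(1 - lag):n]
  }
  if (sd(a) == 0 || sd(b) == 0) return(-Inf)
  cor(a, b)
}

#' Shift a series in time by linear interpolation
#'
#' Evaluates the signal at `t + delay` on the original grid, padding edges
#' with the endpoint values, so that a channel lagging the reference by
#' `delay` is re-aligned by `shiftByDelay(x, delay, fs)`.
#'
#' @param x numeric series.
#' @param delay shift (s); positive moves the series earlier.
#' @param fs sampling rate (Hz).
#' @return shifted series, same length.
#' @export
shiftByDelay <- function(x, delay, fs) {
  if (delay == 0) return(x)
  n <- length(x)
  if (abs(delay) * fs >= n) stop("|delay| must be below the signal duration")
  idx <- seq_len(n) + delay * fs
  approx(seq_len(n), x, xout = idx, rule = 2)$y
}

#' Latent common signal of the short-separation channels
#'
#' One-factor summary of systemic physiology shared by the short channels:
#' the leading eigencomponent of their correlation matrix, i.e. the factor
#' scores of a one-factor model on standardized channels, scaled to unit
#' variance with sign fixed so the mean loading is positive. Flat channels
#' are excluded with a warning.
#'
#' @param x numeric matrix, channels x time.
#' @return numeric vector (time) with attributes `"loadings"` and
#'   `"explained"` (fraction of variance carried by the factor), or `NULL`
#'   if fewer than 2 channels are usable.
#' @export
latentCommonSignal <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 2) stop("need at least 2 short channels")
  sds <- apply(x, 1, sd)
  ok <- sds > .Machine$double.eps^0.5 * pmax(1, abs(rowMeans(x)))
  if (!all(ok)) warning(sum(!ok), " flat short channel(s) excluded")
  if (sum(ok) < 2) return(NULL)
  z <- t(scale(t(x[ok, , drop = FALSE])))
  R <- stats::cor(t(z))
  e <- eigen(R, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (mean(v) < 0) v <- -v
  s <- drop(crossprod(z, v))
  s <- s / sd(s)
  attr(s, "loadings") <- v
  attr(s, "explained") <- e$values[1] / sum(e$values)
  s
}

#' Joint least-squares nuisance regression
#'
#' Residual of `target` after an ordinary least-squares fit on all
#' `regressors` plus an intercept, fitted jointly (order-invariant).
#' Collinear or flat regressors are dropped by the rank-revealing QR solve
#' with a warning.
#'
#' @param target numeric series.
#' @param regressors numeric matrix (columns are regressors) or list of
#'   series; `NULL` or zero usable columns returns the demeaned target.
#' @return residual series, same length as `target`.
#' @export
regressOut <- function(target, regressors) {
  if (is.list(regressors)) regressors <- do.call(cbind, regressors)
  if (is.null(regressors) || NCOL(regressors) == 0)
    return(target - mean(target))
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != length(target))
    stop("regressors must have the same length as the target")
  keep <- apply(regressors, 2, function(cc) sd(cc) > .Machine$double.eps^0.5)
  if (!all(keep)) {
    warning(sum(!keep), " flat regressor(s) dropped")
    regressors <- regressors[, keep, drop = FALSE]
    if (ncol(regressors) == 0) return(target - mean(target))
  }
  X <- cbind(1, regressors)
  fit <- lm.fit(X, target)
  if (fit$rank < ncol(X)) {
    warning("collinear regressor(s) dropped (rank ", fit$rank - 1, " of ",
            ncol(X) - 1, ")")
  }
  unname(fit$residuals)
}

#' Correlation-based signal improvement
#'
#' Removes residual noise shared by oxy- and deoxyhemoglobin under the
#' assumption that the true signals are perfectly anti-correlated:
#' `x0 = (x - alpha * y) / 2` with `alpha = sd(x) / sd(y)` (series are
#' mean-centred first). The implied corrected deoxy series is
#' `-x0 / alpha`, so the corrected pair has Pearson correlation exactly -1.
#'
#' @param hbo,hbr oxy- and deoxyhemoglobin series, equal length.
#' @return list with `HbO` (corrected oxy), `Hb` (implied corrected
#'   deoxy) and `alpha`.
#' @references Cui et al. (2010), NeuroImage 49:3039-3046.
#' @export
cbsi <- function(hbo, hbr) {
  if (length(hbo) != length(hbr)) stop("series must have equal length")
  if (sd(hbr) == 0) stop("zero-variance deoxy series: alpha undefined")
  if (sd(hbo) == 0) stop("zero-variance oxy series")
  x <- hbo - mean(hbo)
  y <- hbr - mean(hbr)
  alpha <- sd(x) / sd(y)
  x0 <- (x - alpha * y) / 2
  list(HbO = x0, Hb = -x0 / alpha, alpha = alpha)
}
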