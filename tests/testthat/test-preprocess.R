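test_that("tddr matches the published reference implementation", {
  d <- read.csv(test_path("tddr-oracle.csv"))
  y <- tddr(d$input, 5.4)
  expect_lt(max(abs(y - d$mne_tddr)), 1e-6)
})

test_that("tddr is near-identity on artifact-free noise", {
  set.seed(101)
  x <- rnorm(500)
  y <- tddr(x, 5.4)
  expect_gt(cor(x, y), 0.95)
})

test_that("tddr suppresses a motion excursion by more than 80%", {
  set.seed(99)
  n <- 600; fs <- 5.4
  clean <- rnorm(n)
  tt <- (0:(n - 1)) / fs
  bump <- 10 * sd(clean) * exp(-((tt - 55) / 1.2)^2)
  y <- tddr(clean + bump, fs)
  resid <- (y - mean(y)) - (clean - mean(clean))
  reduction <- 1 - max(abs(resid[abs(tt - 55) < 4])) / max(abs(bump))
  expect_gt(reduction, 0.8)
})

test_that("tddr keeps constant and all-zero signals unchanged", {
  expect_identical(tddr(rep(0, 100), 5.4), rep(0, 100))
  expect_identical(tddr(rep(3.2, 100), 5.4), rep(3.2, 100))
})

test_that("band-pass preserves in-band tones and rejects drift", {
  fs <- 5.4
  tt <- (0:2999) / fs
  tone <- sin(2 * pi * 1.0 * tt)
  out <- bandpass(tone, "cardiac", fs)
  mid <- 500:2500
  expect_equal(sd(out[mid]) / sd(tone[mid]), 1, tolerance = 0.1)
  drift <- sin(2 * pi * 0.01 * tt)
  att <- sd(bandpass(drift, "cardiac", fs)[mid]) / sd(drift[mid])
  expect_lt(att, 0.1)                     # >= 20 dB down
  expect_equal(bandpass(rep(0, 500), "mayer", fs), rep(0, 500),
               tolerance = 1e-12)
})

test_that("band edges at or above Nyquist are rejected by name", {
  expect_error(bandpass(rnorm(100), list(name = "cardiac", low = 0.5,
                                         high = 3), fs = 5.4),
               "cardiac")
})

test_that("delay estimation recovers injected integer-sample lags", {
  fs <- 5.4
  set.seed(7)
  base <- bandpass(rnorm(3000), "respiration", fs)
  x <- rbind(base, base, c(base[3:3000], base[2999:3000]))  # 2-sample lead
  d <- estimateDelays(x, "respiration", fs)
  expect_equal(unname(d[2] - d[1]), 0, tolerance = 0.5 / fs)
  expect_equal(unname(abs(d[3] - d[1])), 2 / fs, tolerance = 0.5 / fs)
})

test_that("delay estimation matches a brute-force lag scan", {
  fs <- 5.4
  set.seed(21)
  base <- bandpass(rnorm(2000), "mayer", fs)
  lagS <- 4L
  x <- rbind(base, c(rep(base[1], lagS), base[1:(2000 - lagS)]))
  d <- estimateDelays(x, "mayer", fs)
  # brute force on the band-passed signals against their mean
  f1 <- bandpass(x[1, ], "mayer", fs); f2 <- bandpass(x[2, ], "mayer", fs)
  ref <- (f1 + f2) / 2
  scan <- function(s) {
    lags <- -15:15
    cc <- sapply(lags, function(l) {
      n <- length(s)
      if (l >= 0) cor(s[(1 + l):n], ref[1:(n - l)])
      else cor(s[1:(n + l)], ref[(1 - l):n])
    })
    lags[which.max(cc)] / fs
  }
  expect_equal(unname(d[1]), scan(f1), tolerance = 0.5 / fs)
  expect_equal(unname(d[2]), scan(f2), tolerance = 0.5 / fs)
})

test_that("antiphase tones sit half a period apart", {
  fs <- 5.4
  tt <- (0:1999) / fs
  s <- sin(2 * pi * 0.25 * tt)
  x <- rbind(s, -s, s)
  d <- estimateDelays(x, "respiration", fs, maxLag = 2)
  expect_equal(abs(unname(d[2])), 2, tolerance = 0.5 / fs)  # half of 4 s period
  expect_equal(unname(d[1]), 0, tolerance = 0.5 / fs)
})

test_that("interpolation shifts are invertible and degrade to indexing", {
  fs <- 5.4
  tt <- (0:499) / fs
  x <- sin(2 * pi * 0.1 * tt) + 0.3 * cos(2 * pi * 0.05 * tt)
  expect_identical(shiftByDelay(x, 0, fs), x)
  y <- shiftByDelay(shiftByDelay(x, 0.37, fs), -0.37, fs)
  expect_lt(max(abs(y - x)[20:480]), 0.01 * diff(range(x)))
  y2 <- shiftByDelay(x, 3 / fs, fs)
  expect_equal(y2[1:(500 - 3)], x[4:500], tolerance = 1e-12)
  expect_equal(y2[(500 - 2):500], rep(x[500], 3), tolerance = 1e-12)
  expect_error(shiftByDelay(x, 200, fs), "duration")
})

test_that("Beer-Lambert inversion recovers a known forward model exactly", {
  set.seed(3)
  n <- 300
  hbo <- cumsum(rnorm(n, 0, 0.05)); hbo <- hbo - mean(hbo)
  hb <- cumsum(rnorm(n, 0, 0.02)); hb <- hb - mean(hb)
  E <- extinctionCoefficients()[c("745", "850"), ]
  d <- 3; dpf <- c(6, 6)
  od <- rbind((E[1, "HbO"] * hbo + E[1, "Hb"] * hb) * 1e-3 * d * dpf[1],
              (E[2, "HbO"] * hbo + E[2, "Hb"] * hb) * 1e-3 * d * dpf[2])
  I <- 1000 * exp(-od)
  out <- mbll(I, d, dpf, E)
  # I0 is the temporal mean, so recovery is exact up to that baseline
  expect_equal(out$HbO - mean(out$HbO), hbo - mean(hbo), tolerance = 1e-9)
  expect_equal(out$Hb - mean(out$Hb), hb - mean(hb), tolerance = 1e-9)
})

test_that("Beer-Lambert degenerate and scaling behaviour", {
  E <- extinctionCoefficients()[c("745", "850"), ]
  I <- matrix(500, 2, 50)
  out <- mbll(I, 3, c(6, 6), E)
  expect_equal(out$HbO, rep(0, 50))
  expect_equal(out$Hb, rep(0, 50))
  set.seed(4)
  I2 <- matrix(exp(rnorm(100, log(500), 0.01)), 2, 50)
  a <- mbll(I2, 3, c(6, 6), E)
  b <- mbll(I2, 3, c(12, 12), E)
  expect_equal(b$HbO, a$HbO / 2, tolerance = 1e-12)
  expect_error(mbll(I2, 3, c(6, 6), matrix(1, 2, 2)), "singular")
  expect_error(mbll(-I2, 3, c(6, 6), E), "positive")
})

test_that("latent common signal recovers a shared factor", {
  set.seed(5)
  n <- 2000
  common <- as.numeric(arima.sim(list(ar = 0.9), n))
  X <- t(sapply(1:5, function(i) common + rnorm(n, 0, sd(common) / sqrt(10))))
  s <- latentCommonSignal(X)
  expect_gt(abs(cor(s, common)), 0.95)
  expect_equal(sd(s), 1, tolerance = 1e-8)
  # identical channels: the factor is the standardized series itself
  X2 <- rbind(common, common, common)
  s2 <- latentCommonSignal(X2)
  expect_equal(as.numeric(s2), as.numeric(scale(common)), tolerance = 1e-8)
  expect_equal(attr(s2, "explained"), 1, tolerance = 1e-8)
})

test_that("orthogonal channels leave the factor near the noise floor", {
  set.seed(6)
  X <- matrix(rnorm(4 * 4000), 4)
  s <- latentCommonSignal(X)
  expect_equal(attr(s, "explained"), 1 / 4, tolerance = 0.1)
})

test_that("flat short channels are excluded with a warning", {
  set.seed(7)
  X <- rbind(rnorm(200), rnorm(200), rep(1, 200))
  expect_warning(latentCommonSignal(X), "flat")
  expect_error(latentCommonSignal(matrix(rnorm(100), 1)), "2 short")
})

test_that("nuisance regression equals the normal-equations solution", {
  set.seed(8)
  n <- 400
  R <- matrix(rnorm(3 * n), n)
  y <- rnorm(n)
  r <- regressOut(y, R)
  X <- cbind(1, R)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(max(abs(r - (y - X %*% beta))), 1e-10)
})

test_that("regression handles span, orthogonality and collinearity", {
  set.seed(9)
  n <- 600
  R <- matrix(rnorm(2 * n), n)
  y <- drop(R %*% c(2, -1)) + 5
  expect_lt(sqrt(mean(regressOut(y, R)^2)), 1e-8 * sqrt(mean(y^2)))
  tt <- (0:(n - 1)) / n
  s1 <- sin(2 * pi * 5 * tt); c1 <- cos(2 * pi * 5 * tt)
  expect_equal(regressOut(c1 + 3, cbind(s1)), c1 - mean(c1), tolerance = 1e-8)
  expect_warning(r2 <- regressOut(y, cbind(R, R[, 1])), "collinear")
  expect_lt(sqrt(mean(r2^2)), 1e-8 * sqrt(mean(y^2)))
  expect_warning(regressOut(y, cbind(R, 0)), "flat")
})

test_that("CBSI enforces exact anti-correlation and is a fixed point on anti-correlated input", {
  set.seed(10)
  x <- cumsum(rnorm(300)); x <- x - mean(x)
  y <- -x / 2                       # alpha = sd(x)/sd(y) = 2
  out <- cbsi(x, y)
  expect_equal(out$HbO, x, tolerance = 1e-10)
  expect_equal(cor(out$HbO, out$Hb), -1, tolerance = 1e-12)
  x2 <- rnorm(300); y2 <- rnorm(300)
  out2 <- cbsi(x2, y2)
  expect_lt(var(out2$HbO), var(x2))
  expect_equal(cor(out2$HbO, out2$Hb), -1, tolerance = 1e-12)
  expect_error(cbsi(x2, rep(1, 300)), "alpha")
})
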