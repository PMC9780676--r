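# build a CleanSeries by hand with known per-channel series
makeClean <- function(values, fs = 5.4, onsets = c(10, 60), task_s = 10) {
  m <- m1Montage()
  long <- m[m$pathType == "long", ]
  n <- round((max(onsets) + 50) * fs)
  mat <- matrix(rep(values, each = n), nrow = 16, byrow = TRUE)
  tt <- (seq_len(n) - 1) / fs
  for (ch in 1:16) mat[ch, ] <- values[ch] * tt
  onsetIdx <- round(onsets * fs) + 1L
  segEnd <- c(onsetIdx[-1] - 1L, n)
  for (k in seq_along(onsetIdx)) {
    seg <- onsetIdx[k]:segEnd[k]
    mat[, seg] <- mat[, seg] - mat[, onsetIdx[k]]
  }
  rownames(mat) <- long$channel
  new("CleanSeries", SummarizedExperiment(
    assays = list(clean = mat), rowData = long,
    metadata = list(fs = fs,
                    events = data.frame(onset = onsets, duration = task_s),
                    participant = "P01", lesionSide = "left",
                    stageLog = list())))
}

test_that("epoching yields trials x channels windows of the right size", {
  clean <- makeClean(rep(1, 16))
  ep <- epochTrials(clean)
  expect_equal(dim(ep), c(2L, 16L, round(10 * 5.4)))
  expect_true(all(ep[, , 1] == 0))        # onset sample is the baseline
})

test_that("epoching rejects onsets beyond the end and overlapping windows", {
  clean <- makeClean(rep(1, 16))
  md <- metadata(clean)
  md$events <- data.frame(onset = c(10, 1e5), duration = 10)
  metadata(clean) <- md
  expect_error(epochTrials(clean), "beyond")
  md$events <- data.frame(onset = c(10, 15), duration = 10)
  metadata(clean) <- md
  expect_error(epochTrials(clean), "overlap")
})

test_that("task slope matches the least-squares closed form", {
  fs <- 5.4
  tt <- (0:53) / fs
  expect_equal(taskSlope(2.5 * tt, fs = fs), 2.5, tolerance = 1e-12)
  expect_equal(taskSlope(rep(1.3, 54), fs = fs), 0)
  set.seed(31)
  x <- 0.7 * tt + rnorm(54, 0, 0.2)
  oracle <- unname(coef(lm(x ~ tt))[2])
  expect_equal(taskSlope(x, fs = fs), oracle, tolerance = 1e-10)
  expect_error(taskSlope(1, fs = fs), "2 samples")
})

test_that("laterality is the contralesional minus ipsilesional slope", {
  # left-lesion: ipsilesional = left hemisphere
  slopes <- matrix(1.0, nrow = 3, ncol = 16)
  m <- m1Montage()
  long <- as.data.frame(m[m$pathType == "long", ])
  colnames(slopes) <- long$channel
  slopes[, long$channel[long$hemisphere == "right"]] <- 1.5
  lat <- m1Laterality(slopes, m, lesion_side = "left")
  expect_equal(unname(lateralityValues(lat)),
               matrix(0.5, 3, 8), ignore_attr = TRUE)
  # identical hemispheres: all zero
  lat0 <- m1Laterality(matrix(2, 2, 16,
                              dimnames = list(NULL, long$channel)),
                       m, lesion_side = "right")
  expect_true(all(lateralityValues(lat0) == 0))
})

test_that("swapping the lesion side negates every value", {
  set.seed(33)
  m <- m1Montage()
  long <- as.data.frame(m[m$pathType == "long", ])
  slopes <- matrix(rnorm(5 * 16), 5, 16, dimnames = list(NULL, long$channel))
  a <- lateralityValues(m1Laterality(slopes, m, "left"))
  b <- lateralityValues(m1Laterality(slopes, m, "right"))
  expect_equal(a, -b)
  expect_equal(ncol(a), 8L)
  expect_equal(nrow(a), 5L)               # trial count conserved
})

test_that("a missing pair member flags NA, not zero", {
  m <- m1Montage()
  long <- as.data.frame(m[m$pathType == "long", ])
  slopes <- matrix(1, 2, 15,
                   dimnames = list(NULL, setdiff(long$channel, "L_l_8")))
  lat <- m1Laterality(slopes, m, "left")
  v <- lateralityValues(lat)
  expect_true(all(is.na(v[, "pair_8"])))
  expect_true(all(v[, 1:7] == 0))
})

test_that("typical lateralization is negative under this sign convention", {
  # paretic-hand movement drives the ipsilesional motor cortex hardest, so
  # a typically lateralized participant has ipsi > contra slopes
  m <- m1Montage()
  long <- as.data.frame(m[m$pathType == "long", ])
  slopes <- matrix(0.5, 1, 16, dimnames = list(NULL, long$channel))
  slopes[, long$channel[long$hemisphere == "left"]] <- 1.0  # lesion left
  lat <- m1Laterality(slopes, m, lesion_side = "left")
  expect_true(all(lateralityValues(lat) < 0))
})
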