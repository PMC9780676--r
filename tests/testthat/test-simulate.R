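test_that("recordings are deterministic given config and seed", {
  cfg <- simConfig(n_participants = 2, n_trials = 2, seed = 42)
  tr <- cohortTruth(cfg)
  r1 <- generateRecording(cfg, tr, 1, seed = 7)
  r2 <- generateRecording(cfg, tr, 1, seed = 7)
  expect_identical(assay(r1, "wl1"), assay(r2, "wl1"))
  expect_identical(assay(r1, "wl2"), assay(r2, "wl2"))
  r3 <- generateRecording(cfg, tr, 1, seed = 8)
  expect_false(identical(assay(r1, "wl1"), assay(r3, "wl1")))
})

test_that("recording length follows the trial arithmetic", {
  cfg <- simConfig(n_participants = 1, n_trials = 4, task_s = 10,
                   rest_s = 40, lead_in_s = 30, fs = 5.4, seed = 1)
  rec <- generateRecording(cfg, cohortTruth(cfg), 1, seed = 2)
  expect_equal(ncol(rec), round((30 + 4 * 50) * 5.4))
  expect_equal(taskOnsets(rec), 30 + (0:3) * 50)
  expect_equal(samplingRate(rec), 5.4)
})

test_that("null generator yields constant baseline intensity", {
  cfg <- simConfig(n_participants = 1, n_trials = 2, hrf_amplitude = 0,
                   band_amplitudes = c(cardiac = 0, respiration = 0, mayer = 0),
                   sensor_noise_od = 0, motion_rate = 0, seed = 5)
  rec <- generateRecording(cfg, cohortTruth(cfg), 1, seed = 6)
  w <- assay(rec, "wl1")
  expect_true(all(apply(w, 1, function(x) diff(range(x))) == 0))
})

test_that("a missing seed is an error", {
  cfg <- simConfig(n_participants = 1, seed = 1)
  tr <- cohortTruth(cfg)
  expect_error(generateRecording(cfg, tr, 1), "seed")
})

test_that("item generator matches closed-form category probabilities", {
  cuts <- list(c(-0.5, 0.8))
  draws <- vapply(1:4000, function(s)
    generateItemResponses(0, 0, cuts, "FM12", seed = s)$response, numeric(1))
  freq <- tabulate(draws + 1L, nbins = 3) / 4000
  expected <- diff(c(0, pnorm(c(-0.5, 0.8)), 1))
  expect_equal(freq, expected, tolerance = 0.05)
})

test_that("symmetric cutpoints give the closed-form middle probability", {
  # at rho = 0 and latent 0 the propensity is standard normal, so the
  # middle-category mass is the Phi(c) - Phi(-c) closed form
  cc <- 0.9
  draws <- vapply(1:4000, function(s)
    generateItemResponses(0, 0, list(c(-cc, cc)), "FM12", seed = s)$response,
    numeric(1))
  expect_equal(mean(draws == 1), pnorm(cc) - pnorm(-cc), tolerance = 0.05)
  # a fully-coupled link at latent 0 is degenerate at the middle category
  d1 <- vapply(1:50, function(s)
    generateItemResponses(0, 1, list(c(-cc, cc)), "FM12", seed = s)$response,
    numeric(1))
  expect_true(all(d1 == 1))
})

test_that("extreme latent traits saturate at the top category", {
  r <- generateItemResponses(50, 0.9, defaultCutpoints("SISHand"),
                             "SISHand", seed = 1)
  expect_true(all(r$response == 5))
  expect_error(generateItemResponses(0, 1.5, list(c(0, 1)), "FM12", seed = 1),
               "rho")
  expect_error(generateItemResponses(0, 0.5, list(c(1, 0)), "FM12", seed = 1),
               "increasing")
})

test_that("default cohort matches the study scale: 11 x (12 + 5)", {
  cfg <- simConfig(n_trials = 2, seed = 3)   # short recordings, study-size cohort
  cohort <- generateCohort(cfg)
  expect_length(cohort$recordings, 11L)
  expect_equal(nrow(cohort$items), 11L * 17L)
  expect_equal(unname(table(cohort$items$instrument)), c(11L * 12L, 11L * 5L),
               ignore_attr = TRUE)
  # determinism of the whole cohort
  cohort2 <- generateCohort(cfg)
  expect_identical(cohort$items, cohort2$items)
  expect_identical(assay(cohort$recordings[[4]], "wl1"),
                   assay(cohort2$recordings[[4]], "wl1"))
})

test_that("latent links have the configured slopes and vanish at rho = 0", {
  cfg0 <- simConfig(n_participants = 4000, true_rho_m1lat = 0, seed = 8)
  t0 <- cohortTruth(cfg0)
  expect_lt(abs(cor(t0$ue, t0$eta_m1)), 0.05)
  cfg1 <- simConfig(n_participants = 4000, true_rho_m1lat = 0.6, seed = 8)
  t1 <- cohortTruth(cfg1)
  slope <- coef(stats::lm(t1$eta_m1 ~ t1$ue))[2]
  expect_equal(unname(slope), 0.6, tolerance = 0.05)
  # monotone link into the item propensities: larger trait, higher scores
  hi <- generateItemResponses(3, 0.8, defaultCutpoints("FM12"), "FM12", seed = 2)
  lo <- generateItemResponses(-3, 0.8, defaultCutpoints("FM12"), "FM12", seed = 2)
  expect_true(all(hi$response >= lo$response))
  expect_gt(sum(hi$response), sum(lo$response))
})

test_that("physiological components keep >=90% of power in their band", {
  for (b in c("cardiac", "respiration", "mayer")) {
    amps <- c(cardiac = 0, respiration = 0, mayer = 0)
    amps[b] <- 1
    cfg <- simConfig(n_participants = 1, n_trials = 3, hrf_amplitude = 0,
                     band_amplitudes = amps, sensor_noise_od = 0,
                     motion_rate = 0, seed = 13)
    rec <- generateRecording(cfg, cohortTruth(cfg), 1, seed = 14)
    x <- -log(assay(rec, "wl1")[1, ])       # back to attenuation
    s <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = TRUE)
    f <- s$freq * cfg$fs
    bd <- defaultBands(); bd <- bd[bd$name == b, ]
    inBand <- sum(s$spec[f >= bd$low & f <= bd$high]) / sum(s$spec)
    expect_gt(inBand, 0.9)
  }
})
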