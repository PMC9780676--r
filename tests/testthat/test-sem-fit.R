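test_that("model building validates its inputs", {
  cfg <- simConfig(n_participants = 3, n_trials = 3, seed = 51)
  truth <- cohortTruth(cfg)
  items <- cohortItems(truth, cfg, seedBase = 900L)
  y <- simulateLateralityTrials(truth, seed = 52)
  expect_s3_class(buildSemModel(items, y), "SemModel")
  expect_error(buildSemModel(items, y[1:2, , ]), "matching")
  bad <- items[items$item != 3 | items$instrument != "FM12", ]
  expect_error(buildSemModel(bad, y), "missing item")
})

test_that("unit-variance identity holds for any loading", {
  lam <- runif(20)
  expect_equal(lam^2 + (1 - lam^2), rep(1, 20))
  # and in the fitted draws: sub-trait residual sd is tied to the loading
  post <- smallFit()
  d <- post@draws
  expect_true(all(d[, "rho_fm"] > 0 & d[, "rho_fm"] < 1))
  expect_true(all(d[, "rho_sis"] > 0 & d[, "rho_sis"] < 1))
  expect_true(all(abs(d[, "rho_m1lat"]) < 1))
  loads <- d[, sprintf("loading[%d]", 1:8)]
  expect_true(all(loads > 0 & loads < 1))
  expect_true(all(d[, "df_lat"] > 0 & d[, "df_lat"] < 30))
  expect_true(all(d[, "df_trial"] > 0 & d[, "df_trial"] < 30))
})

test_that("sampling is reproducible under a fixed seed", {
  cfg <- simConfig(n_participants = 3, n_trials = 3, seed = 53)
  truth <- cohortTruth(cfg)
  items <- cohortItems(truth, cfg, seedBase = 910L)
  y <- simulateLateralityTrials(truth, seed = 54)
  model <- buildSemModel(items, y)
  p1 <- fitSem(model, chains = 2, adapt = 100, warmup = 50, draws = 100,
               seed = 7, monitors = c("rho_m1lat", "df_trial"))
  p2 <- fitSem(model, chains = 2, adapt = 100, warmup = 50, draws = 100,
               seed = 7, monitors = c("rho_m1lat", "df_trial"))
  expect_identical(p1@draws, p2@draws)
  p3 <- fitSem(model, chains = 2, adapt = 100, warmup = 50, draws = 100,
               seed = 8, monitors = c("rho_m1lat", "df_trial"))
  expect_false(identical(p1@draws, p3@draws))
})

test_that("prior-only sampling reproduces the scaled-Beta DF prior", {
  cfg <- simConfig(n_participants = 3, n_trials = 3, seed = 55)
  truth <- cohortTruth(cfg)
  items <- cohortItems(truth, cfg, seedBase = 920L)
  y <- simulateLateralityTrials(truth, seed = 56)
  model <- buildSemModel(items, y, priorOnly = TRUE)
  post <- fitSem(model, chains = 2, adapt = 200, warmup = 100, draws = 1500,
                 seed = 9, monitors = c("df_trial", "rho_m1lat"))
  q <- quantile(post@draws[, "df_trial"], c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(q, 30 * qbeta(c(0.25, 0.5, 0.75), 2, 2), tolerance = 0.06)
  # flat prior on the unconstrained-influence parameter
  expect_equal(mean(post@draws[, "rho_m1lat"]), 0, tolerance = 0.1)
})

test_that("summaries match an independent quantile oracle and nest", {
  post <- smallFit()
  s <- summarizeSem(post)
  cc <- s$correlations
  for (p in c("rho_fm", "rho_sis", "rho_m1lat")) {
    v <- post@draws[, p]
    row <- cc[cc$parameter == p, ]
    expect_equal(row$median, manualQuantile(v, 0.5), tolerance = 1e-10)
    expect_equal(row$q2.5, manualQuantile(v, 0.025), tolerance = 1e-10)
    expect_equal(row$q97.5, manualQuantile(v, 0.975), tolerance = 1e-10)
  }
  expect_true(all(cc$q25 >= cc$q2.5 & cc$q75 <= cc$q97.5))
  expect_true(all(cc$q25 <= cc$median & cc$median <= cc$q75))
  # per-participant scores exist for every participant and sub-trait
  expect_equal(nrow(s$participantScores), 5L * 3L)
  expect_length(s$loadingMedians, 8L)
})

test_that("the influence difference is computed draw-wise", {
  draws <- cbind(rho_fm = c(0.1, 0.9), rho_sis = c(0.9, 0.1),
                 rho_m1lat = c(0, 0))
  post <- new("SemPosterior", draws = draws, chain = c(1L, 1L),
              iteration = 1:2, info = list(participants = character(0)))
  s <- summarizeSem(post)
  diffRow <- s$correlations[s$correlations$parameter == "rho_sis_minus_fm", ]
  expect_equal(diffRow$median, 0)          # draw-wise: (+0.8, -0.8)
  expect_equal(diffRow$q97.5, manualQuantile(c(0.8, -0.8), 0.975))
})

test_that("diagnostics gate blocks summaries unless forced", {
  post <- smallFit()
  bad <- new("SemDiagnostics",
             table = data.frame(param = "x", rhat = 2, tailESS = 5),
             nDivergent = 0L, rhatLimit = 1.01, essFloor = 100, pass = FALSE)
  expect_error(summarizeSem(post, diagnostics = bad), "diagnostics")
  expect_s3_class(summarizeSem(post, diagnostics = bad, force = TRUE),
                  "semSummary")
})
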