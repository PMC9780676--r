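# shared fixtures: small configs, item helpers, and a cache so expensive
# MCMC fits can be reused across test blocks

noiseFreeConfig <- function(n_participants = 1, n_trials = 3, seed = 3) {
  simConfig(n_participants = n_participants, n_trials = n_trials,
            band_amplitudes = c(cardiac = 0, respiration = 0, mayer = 0),
            sensor_noise_od = 0, motion_rate = 0, short_hrf_fraction = 0,
            seed = seed)
}

cohortItems <- function(truth, cfg, seedBase) {
  do.call(rbind, lapply(seq_len(cfg$n_participants), function(i) rbind(
    generateItemResponses(truth$ue[i], cfg$true_rho_fm,
                          truth$cutpoints$FM12, "FM12",
                          sprintf("P%02d", i), seed = seedBase + i),
    generateItemResponses(truth$ue[i], cfg$true_rho_sis,
                          truth$cutpoints$SISHand, "SISHand",
                          sprintf("P%02d", i), seed = seedBase + 500L + i))))
}

# one small fitted posterior, shared by the fit/summary/diagnostics tests
.fitCache <- new.env(parent = emptyenv())

smallFit <- function() {
  if (!is.null(.fitCache$post)) return(.fitCache$post)
  cfg <- simConfig(n_participants = 5, n_trials = 5, seed = 11)
  truth <- cohortTruth(cfg)
  y <- simulateLateralityTrials(truth, seed = 12)
  items <- cohortItems(truth, cfg, seedBase = 4000L)
  model <- buildSemModel(items, y)
  .fitCache$model <- model
  .fitCache$post <- fitSem(model, chains = 2, adapt = 150, warmup = 100,
                           draws = 250, seed = 5)
  .fitCache$post
}

# recovery fits at the study scale (30 participants x 20 trials); cached so
# the coverage and spatial-ordering checks share them
recoveryFit <- function(truthRho, seed) {
  key <- sprintf("rec_%s_%d", truthRho, seed)
  if (!is.null(.fitCache[[key]])) return(.fitCache[[key]])
  cfg <- simConfig(n_participants = 30L, n_trials = 20L,
                   true_rho_m1lat = truthRho, seed = seed)
  truth <- cohortTruth(cfg)
  y <- simulateLateralityTrials(truth, seed = seed + 1L)
  items <- cohortItems(truth, cfg, seedBase = seed + 100L)
  model <- buildSemModel(items, y)
  post <- fitSem(model, chains = 2, adapt = 300, warmup = 200, draws = 500,
                 seed = seed, monitors = c("rho_m1lat", "loading"))
  .fitCache[[key]] <- post
  post
}

manualQuantile <- function(v, p) {
  # independent sort-based quantile (linear interpolation of order stats)
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}
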