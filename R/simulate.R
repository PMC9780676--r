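#' Study-design configuration for the synthetic cohort generator
#'
#' Collects every knob of the synthetic home-fNIRS study in one validated
#' list. Defaults emulate the study conditions the analysis targets: 11
#' participants each performing 10 trials of a 10 s fist-squeeze task
#' followed by 40 s rest, recorded at 5.4 Hz on the 8 x 2 montage, with a
#' 30 s lead-in rest so filters and baselines have context.
#'
#' @param n_participants cohort size.
#' @param n_trials trials per participant.
#' @param task_s,rest_s,lead_in_s task, rest and lead-in durations (s).
#' @param fs sampling rate (Hz).
#' @param band_amplitudes named numeric: amplitude (uM, oxyhemoglobin
#'   scale) of the cardiac, respiration and Mayer-wave oscillations.
#' @param band_freqs named numeric: oscillation frequency (Hz) per band;
#'   must lie inside the nominal band.
#' @param band_delay_range named numeric: half-width (s) of the uniform
#'   per-channel delay of each band's oscillation.
#' @param hrf_amplitude peak oxyhemoglobin response (uM) of the bilateral
#'   task response; `0` disables the task response (and with it any
#'   laterality asymmetry).
#' @param hrf_peak_s peak time (s) of the canonical response.
#' @param laterality_link slope (uM/s per unit latent location score)
#'   mapping the latent laterality structure into the hemispheric slope
#'   asymmetry of the recording.
#' @param pair_loadings length-8 loadings in (0,1) linking the latent
#'   M1-LAT sub-trait to each homotopic pair, ordered medial to lateral.
#'   The default increases laterally, emulating the hand-area topology.
#' @param true_rho_fm,true_rho_sis,true_rho_m1lat generative correlations
#'   between the latent upper-extremity trait and the FM-12, SIS-Hand and
#'   M1-LAT sub-traits. The first two must be in \[0, 1); the laterality
#'   one in (-1, 1).
#' @param latent_df degrees of freedom of the Student-t latent trait.
#' @param trial_noise_sd typical trial-to-trial noise scale (latent
#'   location units) of the laterality data.
#' @param trial_noise_df degrees of freedom of the Student-t trial noise.
#' @param noise_lv_sd spread of per-(participant, location) log-variances
#'   around `2*log(trial_noise_sd)`.
#' @param hb_ratio deoxy/oxy amplitude ratio of the neuronal response
#'   (negative: the classic anti-correlated deoxy dip).
#' @param phys_hb_ratio deoxy/oxy amplitude ratio of systemic
#'   oscillations (positive: systemic physiology moves both together).
#' @param short_hrf_fraction fraction of the long-channel response gain
#'   leaking into short channels (kept at or below 0.1).
#' @param sensor_noise_od Gaussian sensor noise, optical-density units.
#' @param motion_rate motion artifacts per minute.
#' @param motion_amplitude_od typical artifact amplitude (OD units).
#' @param dpf differential pathlength factors for the two wavelengths.
#' @param baseline_intensity detector counts at rest for long and short
#'   channels (named vector).
#' @param seed integer seed; every generator call is reproducible from it.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_participants = 11L,
                      n_trials = 10L,
                      task_s = 10,
                      rest_s = 40,
                      lead_in_s = 30,
                      fs = 5.4,
                      band_amplitudes = c(cardiac = 0.4, respiration = 0.25,
                                          mayer = 0.3),
                      band_freqs = c(cardiac = 1.1, respiration = 0.25,
                                     mayer = 0.08),
                      band_delay_range = c(cardiac = 0.2, respiration = 0.5,
                                           mayer = 1.0),
                      hrf_amplitude = 1.0,
                      hrf_peak_s = 6,
                      laterality_link = 0.03,
                      pair_loadings = seq(0.3, 0.9, length.out = 8),
                      true_rho_fm = 0.7,
                      true_rho_sis = 0.85,
                      true_rho_m1lat = 0.44,
                      latent_df = 15,
                      trial_noise_sd = 1.0,
                      trial_noise_df = 8,
                      noise_lv_sd = 0.5,
                      hb_ratio = -1 / 3,
                      phys_hb_ratio = 0.3,
                      short_hrf_fraction = 0.05,
                      sensor_noise_od = 2e-3,
                      motion_rate = 0.5,
                      motion_amplitude_od = 0.05,
                      dpf = c(6.0, 6.0),
                      baseline_intensity = c(long = 1000, short = 2000),
                      seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' @rdname simConfig
#' @param config a `SimConfig`.
#' @export
validateSimConfig <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with(config, {
    if (n_trials < 1) stop("n_trials must be >= 1")
    if (fs <= 0) stop("fs must be positive")
    if (true_rho_fm < 0 || true_rho_fm >= 1 || true_rho_sis < 0 || true_rho_sis >= 1)
      stop("true_rho_fm and true_rho_sis must lie in [0, 1)")
    if (abs(true_rho_m1lat) > 1) stop("|true_rho_m1lat| must be <= 1")
    if (length(pair_loadings) != 8 || any(pair_loadings <= 0 | pair_loadings >= 1))
      stop("pair_loadings must be 8 values in (0, 1)")
    if (!all(names(band_amplitudes) %in% c("cardiac", "respiration", "mayer")))
      stop("band_amplitudes must be named cardiac/respiration/mayer")
    if (is.null(seed)) stop("a seed is required: generation must be reproducible")
  })
  invisible(config)
}

# evaluate code under a temporary RNG state seeded with `seed`
withSeed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed))
    stop("a seed is required: generation must be reproducible")
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

#' Default ordinal item cutpoints
#'
#' FM-12: 12 items with 3 ordered categories scored 0-2 (two cutpoints per
#' item); SIS-Hand: 5 items with 5 ordered categories scored 1-5 (four
#' cutpoints). Cutpoints sit on the standard-normal propensity scale and
#' drift deterministically across items so items differ in bias.
#'
#' @param instrument `"FM12"` or `"SISHand"`.
#' @return list of strictly increasing cutpoint vectors, one per item.
#' @export
defaultCutpoints <- function(instrument = c("FM12", "SISHand")) {
  instrument <- match.arg(instrument)
  if (instrument == "FM12")
    lapply(1:12, function(j) c(-0.7, 0.7) + (j - 6.5) * 0.08)
  else
    lapply(1:5, function(j) c(-1.2, -0.4, 0.4, 1.2) + (j - 3) * 0.1)
}

.instrumentInfo <- function(instrument) {
  switch(instrument,
    FM12 = list(nItems = 12L, nCats = 3L, firstCat = 0L),
    SISHand = list(nItems = 5L, nCats = 5L, firstCat = 1L),
    stop("unknown instrument: ", instrument))
}

#' Draw the latent ground truth of a synthetic cohort
#'
#' Draws, per participant: the latent upper-extremity impairment/function
#' trait (unit-scale Student-t), the latent M1-LAT sub-trait
#' (`rho * trait` plus Normal residual of variance `1 - rho^2`), eight
#' per-location latent scores through the pair loadings, and
#' per-(participant, location) log-variances of trial noise. The true
#' per-pair M1-LAT mean, in slope units, is `laterality_link` times the
#' location score.
#'
#' @param config a [simConfig()].
#' @param seed optional override of `config$seed`.
#' @return list of class `"SimTruth"`: `ue`, `eta_m1`, `loc` (n x 8),
#'   `logVar` (n x 8), `pairMeans` (n x 8, slope units uM/s), `cutpoints`
#'   (per instrument), and the echoed `config`.
#' @export
cohortTruth <- function(config, seed = config$seed) {
  validateSimConfig(config)
  withSeed(seed, {
    n <- config$n_participants
    lam <- config$pair_loadings
    ue <- rt(n, df = config$latent_df)
    rho <- config$true_rho_m1lat
    eta <- rho * ue + sqrt(1 - rho^2) * rnorm(n)
    loc <- sapply(lam, function(l) l * eta + sqrt(1 - l^2) * rnorm(n))
    loc <- matrix(loc, nrow = n)
    lv <- matrix(rnorm(n * 8, 2 * log(config$trial_noise_sd), config$noise_lv_sd),
                 n, 8)
    out <- list(ue = ue, eta_m1 = eta, loc = loc, logVar = lv,
                pairMeans = config$laterality_link * loc,
                cutpoints = list(FM12 = defaultCutpoints("FM12"),
                                 SISHand = defaultCutpoints("SISHand")),
                config = config)
    class(out) <- "SimTruth"
    out
  })
}

#' Generate ordinal item responses from a latent trait
#'
#' For each item a propensity is drawn as
#' `Normal(rho * latent, sqrt(1 - rho^2))` and the response is the number
#' of that item's cutpoints lying below the propensity, offset by the
#' instrument's first category (FM-12 scores 0-2, SIS-Hand 1-5).
#'
#' @param latent participant's latent trait value.
#' @param rho link correlation in \[-1, 1\].
#' @param cutpoints list of strictly increasing cutpoint vectors, one per
#'   item (see [defaultCutpoints()]).
#' @param instrument `"FM12"` or `"SISHand"`.
#' @param participant participant id recorded in the output.
#' @param seed integer seed.
#' @return data.frame with columns `participant_id`, `instrument`, `item`,
#'   `response`.
#' @export
generateItemResponses <- function(latent, rho, cutpoints,
                                  instrument = c("FM12", "SISHand"),
                                  participant = "P01", seed) {
  instrument <- match.arg(instrument)
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  bad <- vapply(cutpoints, function(cc) any(diff(cc) <= 0), logical(1))
  if (any(bad)) stop("cutpoints must be strictly increasing within each item")
  info <- .instrumentInfo(instrument)
  withSeed(seed, {
    resp <- vapply(cutpoints, function(cc) {
      p <- rnorm(1, rho * latent, sqrt(1 - rho^2))
      info$firstCat + sum(p > cc)
    }, numeric(1))
    data.frame(participant_id = participant, instrument = instrument,
               item = seq_along(cutpoints), response = as.integer(resp))
  })
}

#' Draw per-trial laterality data from the cohort truth
#'
#' Trial value for participant i, pair l:
#' `laterality_link * (loc[i, l] + exp(logVar[i, l] / 2) * t_df)`, i.e. the
#' true location score plus heavy-tailed Student-t trial noise, mapped into
#' slope units. This is exactly the data-generating process the latent-trait
#' SEM assumes for its laterality arm.
#'
#' @param truth a [cohortTruth()].
#' @param seed integer seed.
#' @return array `n_participants x n_trials x 8` of M1-LAT values (uM/s).
#' @export
simulateLateralityTrials <- function(truth, seed) {
  stopifnot(inherits(truth, "SimTruth"))
  cfg <- truth$config
  n <- cfg$n_participants; nt <- cfg$n_trials
  withSeed(seed, {
    y <- array(NA_real_, c(n, nt, 8))
    for (i in seq_len(n)) for (l in 1:8) {
      eps <- exp(truth$logVar[i, l] / 2) * rt(nt, df = cfg$trial_noise_df)
      y[i, , l] <- cfg$laterality_link * (truth$loc[i, l] + eps)
    }
    y
  })
}

#' Synthesize one raw two-wavelength recording
#'
#' Builds intensity time series for all 21 channels (16 long + 5 short) of
#' the [m1Montage()] as `baseline * exp(-attenuation)`, so the modified
#' Beer-Lambert stage has an honest forward model to invert. The
#' attenuation carries: the task response (boxcar convolved with the
#' canonical HRF, hemispheric gains split so the contralesional minus
#' ipsilesional slope difference of each homotopic pair equals that
#' trial's laterality value); sinusoidal cardiac/respiration/Mayer
#' oscillations shared across channels up to per-channel delays; Gaussian
#' sensor noise; and optional motion spikes and steps. Short channels
#' carry the full systemic physiology but at most a small fraction of the
#' response gain.
#'
#' @param config a [simConfig()].
#' @param truth a [cohortTruth()] for the cohort.
#' @param participant participant index into `truth`.
#' @param seed integer seed (required).
#' @param lesion_side `"left"` or `"right"`.
#' @param trialValues optional `n_trials x 8` matrix of per-trial M1-LAT
#'   values (uM/s); drawn via [simulateLateralityTrials()] logic when
#'   omitted.
#' @return a [FnirsRecording].
#' @export
generateRecording <- function(config, truth, participant = 1L, seed,
                              lesion_side = "right", trialValues = NULL) {
  validateSimConfig(config)
  if (missing(seed)) stop("a seed is required: generation must be reproducible")
  stopifnot(lesion_side %in% c("left", "right"))
  montage <- m1Montage()
  fs <- config$fs
  nt <- config$n_trials
  cycle <- config$task_s + config$rest_s
  duration <- config$lead_in_s + nt * cycle
  n <- round(duration * fs)
  onsets <- config$lead_in_s + (seq_len(nt) - 1) * cycle
  tgrid <- (seq_len(n) - 1) / fs

  withSeed(seed, {
    if (is.null(trialValues)) {
      trialValues <- matrix(NA_real_, nt, 8)
      for (l in 1:8) {
        eps <- exp(truth$logVar[participant, l] / 2) *
          rt(nt, df = config$trial_noise_df)
        trialValues[, l] <- config$laterality_link *
          (truth$loc[participant, l] + eps)
      }
    }
    hrfArgs <- list(peak = config$hrf_peak_s)
    s0 <- .unitResponseSlope(fs, config$task_s, hrfArgs)
    respLen <- min(n, round((config$task_s + 35) * fs))
    resp <- .taskResponse(fs, config$task_s, respLen, hrfArgs)

    # per-channel oxyhemoglobin gain for each trial
    nCh <- nrow(montage)
    hbo <- matrix(0, nCh, n, dimnames = list(montage$channel, NULL))
    hb <- matrix(0, nCh, n)
    if (config$hrf_amplitude > 0) {
      base <- config$hrf_amplitude * s0
      for (k in seq_len(nt)) {
        i0 <- round(onsets[k] * fs) + 1L
        idx <- i0:min(n, i0 + respLen - 1L)
        seg <- resp[seq_along(idx)]
        for (ch in seq_len(nCh)) {
          row <- montage[ch, ]
          gain <- if (row$pathType == "short") {
            config$short_hrf_fraction * config$hrf_amplitude
          } else {
            m <- trialValues[k, row$pairIndex]
            contra <- row$hemisphere != lesion_side
            (base + (if (contra) m / 2 else -m / 2)) / s0
          }
          hbo[ch, idx] <- hbo[ch, idx] + gain * seg
        }
      }
      hb <- config$hb_ratio * hbo
    }

    # systemic physiological oscillations: common waveform, channel delays
    for (b in names(config$band_amplitudes)) {
      amp <- config$band_amplitudes[[b]]
      if (amp <= 0) next
      f <- config$band_freqs[[b]]
      phase <- runif(1, 0, 2 * pi)
      delays <- runif(nCh, -config$band_delay_range[[b]],
                      config$band_delay_range[[b]])
      for (ch in seq_len(nCh)) {
        osc <- amp * sin(2 * pi * f * (tgrid - delays[ch]) + phase)
        hbo[ch, ] <- hbo[ch, ] + osc
        hb[ch, ] <- hb[ch, ] + config$phys_hb_ratio * osc
      }
    }

    # forward optics: concentration -> optical density -> intensity
    ext <- extinctionCoefficients()
    wl1 <- matrix(0, nCh, n)
    wl2 <- matrix(0, nCh, n)
    for (ch in seq_len(nCh)) {
      row <- montage[ch, ]
      E <- ext[as.character(c(row$wavelength1, row$wavelength2)), ]
      d <- row$separation
      # concentrations are uM; extinction is per (mM cm)
      od1 <- (E[1, "HbO"] * hbo[ch, ] + E[1, "Hb"] * hb[ch, ]) * 1e-3 *
        d * config$dpf[1]
      od2 <- (E[2, "HbO"] * hbo[ch, ] + E[2, "Hb"] * hb[ch, ]) * 1e-3 *
        d * config$dpf[2]
      wl1[ch, ] <- od1
      wl2[ch, ] <- od2
    }

    # motion artifacts: shared events, per-channel amplitude, OD space
    nEvents <- if (config$motion_rate > 0)
      stats::rpois(1, config$motion_rate * duration / 60) else 0L
    if (nEvents > 0) {
      for (e in seq_len(nEvents)) {
        at <- sample.int(n, 1)
        isSpike <- runif(1) < 0.5
        shape <- if (isSpike) {
          tail <- exp(-(0:round(2 * fs)) / (0.5 * fs))
          w <- numeric(n); idx <- at:min(n, at + length(tail) - 1L)
          w[idx] <- tail[seq_along(idx)]; w
        } else {
          w <- numeric(n); w[at:n] <- 1; w
        }
        for (ch in seq_len(nCh)) {
          a <- config$motion_amplitude_od * runif(1, 0.5, 1.5) *
            sample(c(-1, 1), 1)
          wl1[ch, ] <- wl1[ch, ] + a * shape
          wl2[ch, ] <- wl2[ch, ] + a * shape
        }
      }
    }
    if (config$sensor_noise_od > 0) {
      wl1 <- wl1 + matrix(rnorm(nCh * n, 0, config$sensor_noise_od), nCh, n)
      wl2 <- wl2 + matrix(rnorm(nCh * n, 0, config$sensor_noise_od), nCh, n)
    }
    I0 <- ifelse(montage$pathType == "long",
                 config$baseline_intensity[["long"]],
                 config$baseline_intensity[["short"]])
    wl1 <- I0 * exp(-wl1)
    wl2 <- I0 * exp(-wl2)
    dimnames(wl1) <- dimnames(wl2) <- list(montage$channel, NULL)

    events <- data.frame(onset = onsets, duration = config$task_s)
    new("FnirsRecording", SummarizedExperiment(
      assays = list(wl1 = wl1, wl2 = wl2),
      rowData = montage,
      metadata = list(fs = fs, events = events,
                      participant = sprintf("P%02d", participant),
                      lesionSide = lesion_side,
                      trialValues = trialValues,
                      stageLog = list())))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws the cohort ground truth, then per participant: a raw recording
#' (via [generateRecording()], using trial laterality values consistent
#' with the truth) and FM-12 / SIS-Hand item responses (via
#' [generateItemResponses()]). Lesion sides alternate across participants.
#'
#' @param config a [simConfig()].
#' @return list with elements `recordings` (list of [FnirsRecording]),
#'   `items` (data.frame of 17 item responses per participant), `truth`
#'   (the [cohortTruth()], with `lesionSides` and `trialValues` attached).
#' @export
generateCohort <- function(config = simConfig()) {
  validateSimConfig(config)
  truth <- cohortTruth(config)
  n <- config$n_participants
  withSeed(config$seed + 1L, {
    seeds <- sample.int(.Machine$integer.max %/% 2L, 3L * n)
  })
  lesion <- rep(c("right", "left"), length.out = n)
  trialValues <- simulateLateralityTrials(truth, seed = seeds[1] + 17L)
  recordings <- vector("list", n)
  items <- vector("list", n)
  for (i in seq_len(n)) {
    recordings[[i]] <- generateRecording(
      config, truth, participant = i, seed = seeds[i],
      lesion_side = lesion[i], trialValues = matrix(trialValues[i, , ],
                                                    config$n_trials, 8))
    fm <- generateItemResponses(truth$ue[i], config$true_rho_fm,
                                truth$cutpoints$FM12, "FM12",
                                participant = sprintf("P%02d", i),
                                seed = seeds[n + i])
    sis <- generateItemResponses(truth$ue[i], config$true_rho_sis,
                                 truth$cutpoints$SISHand, "SISHand",
                                 participant = sprintf("P%02d", i),
                                 seed = seeds[2 * n + i])
    items[[i]] <- rbind(fm, sis)
  }
  truth$lesionSides <- lesion
  truth$trialValues <- trialValues
  list(recordings = recordings, items = do.call(rbind, items), truth = truth)
}
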