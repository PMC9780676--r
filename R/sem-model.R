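#' Robust pre-scaling of laterality data
#'
#' Centres and scales each homotopic pair's M1-LAT values across all trials
#' and participants with robust estimators: subtract the median, divide by
#' the scaled median absolute deviation (1.4826 x MAD). Pre-scaled data let
#' the SEM's location shift/scale parameters start near (0, 1), which is
#' what their weakly-informed Normal(0,1) / Weibull(2,1) priors assume.
#'
#' @param m1lat numeric array `participants x trials x 8`.
#' @return list with `scaled` (same shape), `center` and `scale`
#'   (per-pair, for the inverse transform).
#' @export
prescaleLaterality <- function(m1lat) {
  stopifnot(length(dim(m1lat)) == 3, dim(m1lat)[3] == 8)
  if (dim(m1lat)[1] * dim(m1lat)[2] < 3)
    stop("need at least 3 values per pair")
  center <- scale_ <- numeric(8)
  out <- m1lat
  for (l in 1:8) {
    v <- as.vector(m1lat[, , l])
    center[l] <- median(v, na.rm = TRUE)
    scale_[l] <- 1.4826 * median(abs(v - center[l]), na.rm = TRUE)
    if (scale_[l] == 0)
      stop("pair ", l, " has zero median absolute deviation; cannot pre-scale")
    out[, , l] <- (m1lat[, , l] - center[l]) / scale_[l]
  }
  list(scaled = out, center = center, scale = scale_)
}

#' Prior density of the Student-t degrees-of-freedom parameters
#'
#' Both degrees-of-freedom parameters carry the prior DF/30 ~ Beta(2, 2):
#' a parabola on (0, 30) peaking at DF = 15. This is its log density,
#' including the 1/30 change-of-variable constant; outside (0, 30) the
#' density is zero.
#'
#' @param df degrees of freedom (vectorized).
#' @return log density values.
#' @export
dfPriorLogDensity <- function(df) {
  out <- rep(-Inf, length(df))
  ok <- df > 0 & df < 30
  out[ok] <- dbeta(df[ok] / 30, 2, 2, log = TRUE) - log(30)
  out
}

#' Induced Dirichlet log prior for ordinal cutpoints
#'
#' The prior on a set of ordinal cutpoints defined by placing a
#' Dirichlet(`alpha`) on the category probabilities they induce under a
#' standard-normal propensity anchored at `anchor`, including the Jacobian
#' of the cutpoint-to-probability map (a product of normal densities at
#' the cutpoints). With the default unit `alpha` this makes every induced
#' probability vector equally likely a priori.
#'
#' @param cutpoints strictly increasing numeric vector (K-1 cutpoints for
#'   K categories).
#' @param anchor anchor point of the propensity distribution.
#' @param alpha Dirichlet concentration, scalar or length K.
#' @return log prior density; `-Inf` for non-increasing cutpoints.
#' @export
inducedDirichletLogPrior <- function(cutpoints, anchor = 0, alpha = 1) {
  if (any(diff(cutpoints) <= 0)) return(-Inf)
  p <- inducedProbabilities(cutpoints, anchor)
  K <- length(p)
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  logDirichlet <- lgamma(sum(alpha)) - sum(lgamma(alpha)) +
    sum((alpha - 1) * log(p))
  logJacobian <- sum(stats::dnorm(cutpoints, mean = anchor, log = TRUE))
  logDirichlet + logJacobian
}

#' @rdname inducedDirichletLogPrior
#' @return `inducedProbabilities()`: the K ordinal category probabilities
#'   induced by the cutpoints (sums to 1).
#' @export
inducedProbabilities <- function(cutpoints, anchor = 0) {
  diff(c(0, pnorm(cutpoints - anchor), 1))
}

#' Ordinal cumulative-probit log likelihood
#'
#' Probability of one ordinal response under a cumulative normal propensity
#' model: the propensity is Normal(`propensityMean`, 1) and the response
#' falls in category k when the propensity lands between cutpoints k-1 and
#' k (with -Inf/+Inf end cuts).
#'
#' @param response observed category (`firstCategory` upward).
#' @param propensityMean mean of the unit-variance normal propensity.
#' @param cutpoints strictly increasing cutpoints (K-1 values).
#' @param firstCategory the lowest category code (0 for FM-12, 1 for
#'   SIS-Hand).
#' @return log likelihood of the response.
#' @export
ordinalLogLik <- function(response, propensityMean, cutpoints,
                          firstCategory = 0L) {
  k <- response - firstCategory + 1L
  K <- length(cutpoints) + 1L
  if (any(k < 1 | k > K)) stop("response outside the category range")
  cuts <- c(-Inf, cutpoints, Inf)
  log(pnorm(cuts[k + 1] - propensityMean) - pnorm(cuts[k] - propensityMean))
}

.semModelTemplate <- function(perParticipantDF = FALSE, priorOnly = FALSE) {
  dfLatent <- if (perParticipantDF) "
  for (i in 1:N) {
    df_lat_raw[i] ~ dbeta(2, 2)
    df_lat[i] <- 30 * df_lat_raw[i]
  }" else "
  df_lat_raw ~ dbeta(2, 2)
  df_lat <- 30 * df_lat_raw"
  ueDF <- if (perParticipantDF) "df_lat[i]" else "df_lat"
  lik <- function(s) if (priorOnly) "" else s
  paste0("
model {", dfLatent, "
  df_trial_raw ~ dbeta(2, 2)
  df_trial <- 30 * df_trial_raw
  rho_fm ~ dunif(0, 1)
  rho_sis ~ dunif(0, 1)
  rho_m1lat ~ dunif(-1, 1)
  for (l in 1:L) {
    loading[l] ~ dunif(0, 1)
    shift[l] ~ dnorm(0, 1)
    scale[l] ~ dweib(2, 1)
  }
  noise_mu ~ dnorm(0, 1)
  noise_sd ~ dweib(2, 1)
  for (j in 1:J_fm) {
    p_fm[j, 1:K_fm] ~ ddirch(alpha_fm)
    for (k in 1:(K_fm - 1)) { c_fm[j, k] <- qnorm(sum(p_fm[j, 1:k]), 0, 1) }
  }
  for (j in 1:J_sis) {
    p_sis[j, 1:K_sis] ~ ddirch(alpha_sis)
    for (k in 1:(K_sis - 1)) { c_sis[j, k] <- qnorm(sum(p_sis[j, 1:k]), 0, 1) }
  }
  for (i in 1:N) {
    ue[i] ~ dt(0, 1, ", ueDF, ")
    eta_fm[i] ~ dnorm(rho_fm * ue[i], 1 / (1 - rho_fm^2 + 1.0E-10))
    eta_sis[i] ~ dnorm(rho_sis * ue[i], 1 / (1 - rho_sis^2 + 1.0E-10))
    eta_m1[i] ~ dnorm(rho_m1lat * ue[i], 1 / (1 - rho_m1lat^2 + 1.0E-10))
", lik("
    for (j in 1:J_fm) {
      q_fm[i, j, 1] <- phi(c_fm[j, 1] - eta_fm[i])
      for (k in 2:(K_fm - 1)) {
        q_fm[i, j, k] <- phi(c_fm[j, k] - eta_fm[i]) - phi(c_fm[j, k - 1] - eta_fm[i])
      }
      q_fm[i, j, K_fm] <- 1 - phi(c_fm[j, K_fm - 1] - eta_fm[i])
      y_fm[i, j] ~ dcat(q_fm[i, j, 1:K_fm])
    }
    for (j in 1:J_sis) {
      q_sis[i, j, 1] <- phi(c_sis[j, 1] - eta_sis[i])
      for (k in 2:(K_sis - 1)) {
        q_sis[i, j, k] <- phi(c_sis[j, k] - eta_sis[i]) - phi(c_sis[j, k - 1] - eta_sis[i])
      }
      q_sis[i, j, K_sis] <- 1 - phi(c_sis[j, K_sis - 1] - eta_sis[i])
      y_sis[i, j] ~ dcat(q_sis[i, j, 1:K_sis])
    }"), "
    for (l in 1:L) {
      loc[i, l] ~ dnorm(loading[l] * eta_m1[i], 1 / (1 - loading[l]^2 + 1.0E-10))
      lv[i, l] ~ dnorm(noise_mu, 1 / noise_sd^2)", lik("
      for (t in 1:nT) {
        y[i, l, t] ~ dt(shift[l] + scale[l] * loc[i, l], exp(-lv[i, l]), df_trial)
      }"), "
    }
  }
}")
}

#' Build the latent-trait SEM
#'
#' Assembles the hierarchical model linking a latent upper-extremity
#' impairment/function trait (unit-scale Student-t, scaled-Beta prior on
#' its degrees of freedom) to three latent sub-traits: FM-12 and SIS-Hand
#' (positively constrained influences in (0,1)) and M1-LAT (influence free
#' in (-1,1)). Each influence parameter is paired with residual variance
#' `1 - rho^2` so every sub-trait has unit marginal variance and the
#' influence reads as a correlation coefficient. The item sub-traits
#' connect to their ordinal responses through cumulative-probit
#' likelihoods with per-item cutpoints under induced-Dirichlet priors; the
#' laterality sub-trait connects to the 8 measurement locations through
#' positively constrained loadings in (0,1) (again with unit-variance
#' residuals), per-location shift/scale (Normal(0,1) / Weibull(2,1)
#' priors), per-(participant, location) trial-noise log-variances pooled
#' through a hierarchical normal, and a Student-t trial likelihood with a
#' single degrees-of-freedom parameter.
#'
#' @param items item-response table (columns `participant_id`,
#'   `instrument`, `item`, `response`), FM-12 and SIS-Hand rows for every
#'   participant.
#' @param m1lat numeric array `participants x trials x 8` of M1-LAT
#'   values, participant order matching `sort(unique(participant_id))`.
#' @param perParticipantDF give each participant their own latent-trait
#'   degrees of freedom (default: one shared scalar, with the trial
#'   likelihood's DF as the second scalar).
#' @param prescale robustly pre-scale the laterality data per pair
#'   (recommended; see [prescaleLaterality()]).
#' @param priorOnly detach all likelihood terms so the sampler draws from
#'   the joint prior (for prior-predictive checks).
#' @return object of class `"SemModel"`: the JAGS model string, the data
#'   list, monitor names, participant ids and the scaling record.
#' @export
buildSemModel <- function(items, m1lat, perParticipantDF = FALSE,
                          prescale = TRUE, priorOnly = FALSE) {
  participants <- sort(unique(items$participant_id))
  N <- length(participants)
  if (N < 2) stop("need at least 2 participants")
  if (length(dim(m1lat)) != 3 || dim(m1lat)[1] != N || dim(m1lat)[3] != 8)
    stop("m1lat must be a participants x trials x 8 array matching the items")
  fmInfo <- .instrumentInfo("FM12")
  sisInfo <- .instrumentInfo("SISHand")
  getResp <- function(instr, info) {
    sub <- items[items$instrument == instr, ]
    m <- matrix(NA_integer_, N, info$nItems)
    for (r in seq_len(nrow(sub))) {
      i <- match(sub$participant_id[r], participants)
      m[i, sub$item[r]] <- sub$response[r] - info$firstCat + 1L
    }
    if (any(is.na(m))) stop("missing item responses for ", instr)
    if (any(m < 1 | m > info$nCats)) stop("responses out of range for ", instr)
    m
  }
  yFm <- getResp("FM12", fmInfo)
  ySis <- getResp("SISHand", sisInfo)
  scaling <- NULL
  y <- m1lat
  if (prescale) {
    scaling <- prescaleLaterality(m1lat)
    y <- scaling$scaled
  }
  yjags <- aperm(y, c(1, 3, 2))      # participants x locations x trials
  data <- list(y = yjags, y_fm = yFm, y_sis = ySis,
               N = N, L = 8L, nT = dim(y)[2],
               J_fm = fmInfo$nItems, K_fm = fmInfo$nCats,
               J_sis = sisInfo$nItems, K_sis = sisInfo$nCats,
               alpha_fm = rep(1, fmInfo$nCats),
               alpha_sis = rep(1, sisInfo$nCats))
  if (priorOnly) data[c("y", "y_fm", "y_sis", "nT")] <- NULL
  monitors <- c("rho_fm", "rho_sis", "rho_m1lat", "loading", "shift",
                "scale", "noise_mu", "noise_sd", "df_lat", "df_trial",
                "ue", "eta_fm", "eta_sis", "eta_m1", "lv", "c_fm", "c_sis")
  structure(list(model = .semModelTemplate(perParticipantDF, priorOnly),
                 data = data, monitors = monitors,
                 participants = participants, scaling = scaling,
                 perParticipantDF = perParticipantDF, priorOnly = priorOnly),
            class = "SemModel")
}

#' Sample the latent-trait SEM
#'
#' Runs the JAGS Markov chain Monte Carlo sampler on a built model.
#' Reproducible: each chain gets a Mersenne-Twister stream seeded from
#' `seed`, so identical settings yield identical draws.
#'
#' @param model a [buildSemModel()] result.
#' @param chains number of chains (at least 2 for convergence checks).
#' @param adapt,warmup adaptation and burn-in iterations per chain.
#' @param draws retained draws per chain.
#' @param thin thinning interval.
#' @param seed integer seed.
#' @param monitors parameters to record; defaults to the model's list.
#' @param quiet suppress JAGS progress output.
#' @return a [SemPosterior].
#' @export
fitSem <- function(model, chains = 4, adapt = 500, warmup = 500,
                   draws = 1000, thin = 1, seed = 1L, monitors = NULL,
                   quiet = TRUE) {
  stopifnot(inherits(model, "SemModel"))
  if (is.null(monitors)) monitors <- model$monitors
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch))
  adaptComplete <- TRUE
  jm <- withCallingHandlers(
    rjags::jags.model(textConnection(model$model), data = model$data,
                      n.chains = chains, n.adapt = adapt, inits = inits,
                      quiet = quiet),
    warning = function(w) {
      if (grepl("Adaptation incomplete", conditionMessage(w))) {
        adaptComplete <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (warmup > 0)
    update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors, n.iter = draws,
                              thin = thin, progress.bar = "none")
  mats <- lapply(samp, as.matrix)
  drawsMat <- do.call(rbind, mats)
  chainIdx <- rep(seq_len(chains), vapply(mats, nrow, integer(1)))
  iterIdx <- unlist(lapply(mats, function(m) seq_len(nrow(m))))
  new("SemPosterior", draws = drawsMat, chain = as.integer(chainIdx),
      iteration = as.integer(iterIdx),
      info = list(sampler = "JAGS (conjugate/slice MCMC)",
                  seed = as.integer(seed), chains = chains,
                  adapt = adapt, warmup = warmup, nDraws = draws,
                  thin = thin, nDivergent = 0L,
                  adaptComplete = adaptComplete,
                  monitors = monitors,
                  participants = model$participants,
                  scaling = model$scaling))
}
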