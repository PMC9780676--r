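#' Full denoising chain: raw intensities to clean oxyhemoglobin
#'
#' Applies, in order: temporal derivative distribution repair to every
#' intensity channel; per-band inter-channel delay estimation from the
#' short-path 850 nm data (cardiac, respiration, Mayer bands); modified
#' Beer-Lambert conversion to oxy-/deoxyhemoglobin; estimation of the
#' latent common signal of the short channels in four permutations
#' (unfiltered plus the three band-filtered, delay-removed versions,
#' separately for each chromophore) and joint regression of those latent
#' signals out of every long and short channel; joint regression of each
#' long channel's local short channel (again unfiltered plus three
#' band-filtered, delay-removed versions) out of the long data; zero-phase
#' band-pass to the hemodynamic-response band (0.01-0.1 Hz);
#' correlation-based signal improvement; and per-trial baseline correction
#' to the moment of task onset.
#'
#' Every stage preserves the sample count and sampling rate; each stage's
#' parameters are appended to the stage log carried in the result's
#' metadata.
#'
#' @param rec a [FnirsRecording] with task-onset events.
#' @param bands band definitions, see [defaultBands()].
#' @param dpf differential pathlength factors for the two wavelengths.
#' @param stages named logical list to toggle `tddr`, `latent`
#'   (common-signal regression), `shortRegression` and `cbsi`; the
#'   Beer-Lambert conversion, the hemodynamic band-pass and the baseline
#'   correction always run.
#' @param alignTargets if `TRUE`, delays are also removed from the
#'   regression targets (not only from the latent-estimation inputs and
#'   band-filtered regressors, which is the default convention).
#' @return a [CleanSeries] holding denoised oxyhemoglobin for the 16
#'   long-path channels.
#' @export
preprocessRecording <- function(rec, bands = defaultBands(),
                                dpf = c(6.0, 6.0),
                                stages = list(),
                                alignTargets = FALSE) {
  stopifnot(is(rec, "FnirsRecording"))
  st <- utils::modifyList(list(tddr = TRUE, latent = TRUE,
                               shortRegression = TRUE, cbsi = TRUE), stages)
  fs <- samplingRate(rec)
  onsets <- taskOnsets(rec)
  if (is.null(onsets) || length(onsets) == 0)
    stop("recording has no task-onset events")
  n <- ncol(rec)
  if (any(round(onsets * fs) + 1 > n)) stop("events fall outside the recording")
  rd <- rowData(rec)
  isShort <- rd$pathType == "short"
  isLong <- !isShort
  if (!any(isShort)) stop("recording has no short channels mapped")
  log <- list()

  wl1 <- assay(rec, "wl1")
  wl2 <- assay(rec, "wl2")
  if (st$tddr) {
    wl1 <- t(apply(wl1, 1, tddr, fs = fs))
    wl2 <- t(apply(wl2, 1, tddr, fs = fs))
    log$tddr <- list(applied_to = "all intensity channels")
  }

  physBands <- bands[bands$name %in% c("cardiac", "respiration", "mayer"), ]
  delays <- list()
  for (b in physBands$name) {
    delays[[b]] <- suppressWarnings(
      estimateDelays(wl2, b, fs, refRows = which(isShort)))
  }
  log$delays <- list(source = "850 nm, short-path mean reference",
                     bands = physBands$name, values = delays)

  ext <- extinctionCoefficients()
  nCh <- nrow(rec)
  hbo <- matrix(0, nCh, n, dimnames = list(rd$channel, NULL))
  hb <- hbo
  for (ch in seq_len(nCh)) {
    E <- ext[as.character(c(rd$wavelength1[ch], rd$wavelength2[ch])), ]
    conc <- mbll(rbind(wl1[ch, ], wl2[ch, ]), rd$separation[ch], dpf, E)
    hbo[ch, ] <- conc$HbO
    hb[ch, ] <- conc$Hb
  }
  log$mbll <- list(dpf = dpf, extinction = ext)

  shortIdx <- which(isShort)
  chrom <- list(HbO = hbo, Hb = hb)
  if (st$latent) {
    for (cn in names(chrom)) {
      X <- chrom[[cn]]
      latents <- list()
      lat <- suppressWarnings(latentCommonSignal(X[shortIdx, , drop = FALSE]))
      if (!is.null(lat)) latents$unfiltered <- as.numeric(lat)
      for (b in physBands$name) {
        filt <- t(apply(X[shortIdx, , drop = FALSE], 1, function(s) {
          tryCatch(bandpass(s, b, fs), error = function(e) rep(0, n))
        }))
        aligned <- filt
        for (k in seq_along(shortIdx))
          aligned[k, ] <- shiftByDelay(filt[k, ], delays[[b]][shortIdx[k]], fs)
        lat <- suppressWarnings(latentCommonSignal(aligned))
        if (!is.null(lat)) latents[[b]] <- as.numeric(lat)
      }
      if (length(latents)) {
        for (ch in seq_len(nCh)) {
          regs <- latents
          if (alignTargets) {
            # shift each latent signal back into this channel's own time
            # frame instead of leaving the target unshifted
            for (b in intersect(names(regs), physBands$name))
              regs[[b]] <- shiftByDelay(regs[[b]], -delays[[b]][ch], fs)
          }
          X[ch, ] <- suppressWarnings(regressOut(X[ch, ], regs)) +
            mean(X[ch, ])
        }
      }
      chrom[[cn]] <- X
      log$latentCommon[[cn]] <- list(permutations = names(latents))
    }
  }

  if (st$shortRegression) {
    for (cn in names(chrom)) {
      X <- chrom[[cn]]
      for (ch in which(isLong)) {
        sIdx <- which(rd$channel == rd$shortRef[ch])
        s <- X[sIdx, ]
        regs <- list(unfiltered = s)
        for (b in physBands$name) {
          f <- tryCatch(bandpass(s, b, fs), error = function(e) rep(0, n))
          # remove the short channel's own delay, then (optionally) move
          # the regressor into the long channel's time frame
          f <- shiftByDelay(f, delays[[b]][sIdx], fs)
          if (alignTargets) f <- shiftByDelay(f, -delays[[b]][ch], fs)
          regs[[b]] <- f
        }
        tgt <- X[ch, ]
        X[ch, ] <- suppressWarnings(regressOut(tgt, regs)) + mean(tgt)
      }
      chrom[[cn]] <- X
    }
    log$shortRegression <- list(permutations = c("unfiltered", physBands$name))
  }

  bold <- bands[bands$name == "bold", ]
  longIdx <- which(isLong)
  clean <- matrix(0, length(longIdx), n,
                  dimnames = list(rd$channel[longIdx], NULL))
  for (j in seq_along(longIdx)) {
    ch <- longIdx[j]
    ho <- bandpass(chrom$HbO[ch, ], bold, fs)
    hr <- bandpass(chrom$Hb[ch, ], bold, fs)
    clean[j, ] <- if (st$cbsi && sd(hr) > 0 && sd(ho) > 0)
      cbsi(ho, hr)$HbO else ho
  }
  log$bold <- as.list(bold)
  log$cbsi <- list(applied = isTRUE(st$cbsi))

  onsetIdx <- round(onsets * fs) + 1L
  segEnd <- c(onsetIdx[-1] - 1L, n)
  for (k in seq_along(onsetIdx)) {
    seg <- onsetIdx[k]:segEnd[k]
    clean[, seg] <- clean[, seg] - clean[, onsetIdx[k]]
  }
  log$baseline <- list(convention = "per-trial, zero at task onset")

  md <- metadata(rec)
  md$stageLog <- c(md$stageLog, log)
  new("CleanSeries", SummarizedExperiment(
    assays = list(clean = clean),
    rowData = rd[longIdx, ],
    metadata = md))
}
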