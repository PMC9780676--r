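#' Posterior summaries of the latent-trait SEM
#'
#' Medians with central 50% and 95% credible intervals for the three
#' influence (correlation) parameters and for their SIS-minus-FM
#' difference (computed draw-wise, never from marginal summaries);
#' per-participant 25/50/75 posterior percentiles of each latent
#' sub-trait; and the per-location loading medians ordered medial to
#' lateral.
#'
#' @param posterior a [SemPosterior].
#' @param diagnostics optional [SemDiagnostics]; a failing report stops
#'   the summary unless `force = TRUE`.
#' @param force override a failing diagnostics gate.
#' @return list of class `"semSummary"` with elements `correlations`
#'   (data.frame), `participantScores` (data.frame), `loadingMedians`
#'   (length 8), `nDraws`.
#' @export
summarizeSem <- function(posterior, diagnostics = NULL, force = FALSE) {
  stopifnot(is(posterior, "SemPosterior"))
  d <- posterior@draws
  if (nrow(d) == 0) stop("empty posterior")
  if (!is.null(diagnostics) && !diagnostics@pass && !force)
    stop("sampler diagnostics failed; pass force = TRUE to summarize anyway")
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  smry <- function(v) setNames(quantile(v, qs, names = FALSE),
                               c("q2.5", "q25", "median", "q75", "q97.5"))
  rhoPars <- list(rho_fm = d[, "rho_fm"], rho_sis = d[, "rho_sis"],
                  rho_m1lat = d[, "rho_m1lat"],
                  rho_sis_minus_fm = d[, "rho_sis"] - d[, "rho_fm"])
  correlations <- cbind(data.frame(parameter = names(rhoPars)),
                        do.call(rbind, lapply(rhoPars, smry)))
  rownames(correlations) <- NULL

  participants <- posterior@info$participants
  scores <- NULL
  subs <- c(FM12 = "eta_fm", SISHand = "eta_sis", M1LAT = "eta_m1")
  if (all(paste0("eta_fm[", 1, "]") %in% colnames(d))) {
    rows <- list()
    for (i in seq_along(participants)) {
      for (s in names(subs)) {
        col <- sprintf("%s[%d]", subs[[s]], i)
        if (!col %in% colnames(d)) next
        qq <- quantile(d[, col], c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = participants[i], subtrait = s,
          q25 = qq[1], median = qq[2], q75 = qq[3])
      }
    }
    scores <- do.call(rbind, rows)
  }

  loadCols <- sprintf("loading[%d]", 1:8)
  loadings <- if (all(loadCols %in% colnames(d)))
    apply(d[, loadCols, drop = FALSE], 2, median) else NULL
  structure(list(correlations = correlations,
                 participantScores = scores,
                 loadingMedians = unname(loadings),
                 nDraws = nrow(d)),
            class = "semSummary")
}

#' @export
print.semSummary <- function(x, ...) {
  cat("Latent-trait SEM summary (", x$nDraws, " draws)\n", sep = "")
  cc <- x$correlations
  for (r in seq_len(nrow(cc)))
    cat(sprintf("  %-17s median %+.2f  CrI50 [%+.2f, %+.2f]  CrI95 [%+.2f, %+.2f]\n",
                cc$parameter[r], cc$median[r], cc$q25[r], cc$q75[r],
                cc$q2.5[r], cc$q97.5[r]))
  if (!is.null(x$loadingMedians))
    cat("  location loading medians (medial->lateral):",
        paste(sprintf("%.2f", x$loadingMedians), collapse = " "), "\n")
  invisible(x)
}
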