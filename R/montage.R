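#' The 8 x 2 headband montage
#'
#' Builds the measurement geometry of the portable motor-cortex headband: 5
#' detectors spanning the head left-to-right (centre detector on the
#' midline, approximately Cz), 9 long-path sources at 30 mm and 5 short-path
#' sources at 8 mm. The three medial detectors see four long-path sources
#' each and the two lateral end detectors two each, giving exactly 16
#' long-path measurement locations arranged as 8 homotopic pairs -- one
#' channel per hemisphere sharing a medial-to-lateral `pairIndex` (1 =
#' most medial, 8 = most lateral). Each detector also hosts one short-path
#' channel used as a scalp/systemic noise reference; every long channel is
#' mapped to the short channel of its detector.
#'
#' @param shortWavelengths,longWavelengths wavelengths (nm) of the
#'   short-path and long-path LEDs.
#' @return a [S4Vectors::DataFrame] with one row per channel (16 long + 5
#'   short) and columns `channel`, `pathType`, `hemisphere` (`"left"`,
#'   `"right"` or `"midline"` for short channels on the centre detector),
#'   `pairIndex` (1..8 for long channels, `NA` for short), `detector`,
#'   `source`, `separation` (cm), `shortRef`, `wavelength1`, `wavelength2`.
#' @examples
#' m <- m1Montage()
#' sum(m$pathType == "long")            # 16 measurement locations
#' nrow(homotopicPairs(m))              # 8 homotopic pairs
#' @export
m1Montage <- function(longWavelengths = c(745, 850),
                      shortWavelengths = c(735, 850)) {
  # detectors listed medial -> lateral per hemisphere; det 3 is the centre
  det <- data.frame(
    detector = paste0("Det", 1:5),
    side = c("left", "left", "midline", "right", "right"),
    lateral = c(2L, 1L, 0L, 1L, 2L))
  # long channels: centre detector contributes pairIndex 1:2 to each
  # hemisphere; flanking detectors 3:6; end detectors 7:8
  long <- rbind(
    data.frame(detector = "Det3", hemisphere = "left",  pairIndex = 1:2),
    data.frame(detector = "Det3", hemisphere = "right", pairIndex = 1:2),
    data.frame(detector = "Det2", hemisphere = "left",  pairIndex = 3:6),
    data.frame(detector = "Det4", hemisphere = "right", pairIndex = 3:6),
    data.frame(detector = "Det1", hemisphere = "left",  pairIndex = 7:8),
    data.frame(detector = "Det5", hemisphere = "right", pairIndex = 7:8))
  long <- long[order(match(long$hemisphere, c("left", "right")), long$pairIndex), ]
  long$channel <- sprintf("L_%s_%d", substr(long$hemisphere, 1, 1), long$pairIndex)
  long$source <- sprintf("S%02d", seq_len(nrow(long)) %% 9 + 1L)
  long$pathType <- "long"
  long$separation <- 3.0
  long$shortRef <- paste0("SS_", long$detector)
  long$wavelength1 <- longWavelengths[1]
  long$wavelength2 <- longWavelengths[2]
  short <- data.frame(
    detector = det$detector,
    hemisphere = det$side,
    pairIndex = NA_integer_,
    channel = paste0("SS_", det$detector),
    source = paste0("ss", 1:5),
    pathType = "short",
    separation = 0.8,
    shortRef = NA_character_,
    wavelength1 = shortWavelengths[1],
    wavelength2 = shortWavelengths[2])
  out <- DataFrame(rbind(long, short))
  rownames(out) <- out$channel
  validateMontage(out)
  out
}

#' @rdname m1Montage
#' @param montage a montage as returned by [m1Montage()].
#' @return `homotopicPairs()`: a data.frame with columns `pairIndex`,
#'   `left`, `right` (channel ids), ordered medial to lateral.
#' @export
homotopicPairs <- function(montage) {
  long <- as.data.frame(montage[montage$pathType == "long", ])
  out <- data.frame(
    pairIndex = sort(unique(long$pairIndex)),
    left = long$channel[long$hemisphere == "left"][order(long$pairIndex[long$hemisphere == "left"])],
    right = long$channel[long$hemisphere == "right"][order(long$pairIndex[long$hemisphere == "right"])])
  out
}

#' @rdname m1Montage
#' @return `validateMontage()`: the montage, invisibly; errors describe any
#'   violated invariant.
#' @export
validateMontage <- function(montage) {
  long <- montage[montage$pathType == "long", ]
  if (nrow(long) != 16L)
    stop("montage must contain exactly 16 long-path measurement locations, found ",
         nrow(long))
  tab <- table(long$hemisphere, long$pairIndex)
  if (!identical(dim(tab), c(2L, 8L)) || any(tab != 1L))
    stop("montage must form 8 homotopic pairs with one channel per hemisphere")
  if (anyDuplicated(montage$channel))
    stop("channel ids must be unique")
  shorts <- montage$channel[montage$pathType == "short"]
  if (!all(long$shortRef %in% shorts))
    stop("every long channel needs an associated short channel")
  invisible(montage)
}
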