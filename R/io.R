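#' Read and write recordings as a plain-text container
#'
#' Serializes a [FnirsRecording] to a directory holding a JSON header
#' (sampling rate, events, participant metadata, channel table, matrix
#' dimensions) and one full-precision CSV intensity matrix per wavelength
#' -- a SNIRF-inspired layout in text form. The round trip is lossless to
#' the last bit of the printed precision (17 significant digits). All
#' writes are atomic (temp file + rename).
#'
#' @param rec a [FnirsRecording].
#' @param path directory to create/read.
#' @return `writeRecording()`: `path`, invisibly. `readRecording()`: the
#'   reconstructed [FnirsRecording].
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "FnirsRecording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  md <- metadata(rec)
  header <- list(
    format = "fnirsLat-recording/1",
    fs = md$fs,
    participant = md$participant,
    lesionSide = md$lesionSide,
    events = md$events,
    nChannels = nrow(rec),
    nSamples = ncol(rec),
    channels = as.data.frame(rowData(rec)))
  .atomicWrite(file.path(path, "header.json"), function(f)
    jsonlite::write_json(header, f, auto_unbox = TRUE, digits = NA))
  for (a in c("wl1", "wl2")) {
    m <- assay(rec, a)
    .atomicWrite(file.path(path, paste0(a, ".csv")), function(f)
      .writeMatrix(m, f))
  }
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("no recording header at ", path)
  header <- jsonlite::read_json(hf, simplifyVector = TRUE)
  if (is.null(header$events) || NROW(header$events) == 0 ||
      !is.data.frame(header$events))
    stop("recording header has no task events (stimulus block missing)")
  ch <- DataFrame(header$channels)
  rownames(ch) <- ch$channel
  mats <- lapply(c("wl1", "wl2"), function(a) {
    m <- .readMatrix(file.path(path, paste0(a, ".csv")))
    if (!identical(dim(m), c(header$nChannels, header$nSamples)))
      stop("intensity matrix ", a, " is truncated or corrupt")
    rownames(m) <- ch$channel
    m
  })
  bad <- rownames(mats[[1]])[rowSums(mats[[1]] <= 0 | mats[[2]] <= 0) > 0]
  if (length(bad))
    stop("non-positive intensities in channel(s): ", paste(bad, collapse = ", "))
  new("FnirsRecording", SummarizedExperiment(
    assays = list(wl1 = mats[[1]], wl2 = mats[[2]]),
    rowData = ch,
    metadata = list(fs = header$fs, events = as.data.frame(header$events),
                    participant = header$participant,
                    lesionSide = header$lesionSide,
                    stageLog = list())))
}

.writeMatrix <- function(m, f) {
  con <- file(f, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = ","), con)
}

.readMatrix <- function(f) {
  if (!file.exists(f)) stop("missing file: ", f)
  lines <- readLines(f)
  do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])))
}

.atomicWrite <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move ", tmp, " into place")
  invisible(path)
}

#' Read and write ordinal item-response tables
#'
#' CSV with columns `participant_id`, `instrument`, `item`, `response`.
#' Reading validates instrument names, item and category ranges (FM-12:
#' items 1-12 scored 0-2; SIS-Hand: items 1-5 scored 1-5) and rejects
#' duplicated (participant, instrument, item) rows, reporting offending
#' row numbers.
#'
#' @param items item-response data.frame.
#' @param path CSV file path.
#' @export
writeItemResponses <- function(items, path) {
  .atomicWrite(path, function(f)
    write.csv(items, f, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname writeItemResponses
#' @return `readItemResponses()`: the validated data.frame.
#' @export
readItemResponses <- function(path) {
  items <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "instrument", "item", "response")
  if (!all(need %in% names(items)))
    stop("item file must have columns: ", paste(need, collapse = ", "))
  bad <- which(!items$instrument %in% c("FM12", "SISHand"))
  if (length(bad)) stop("unknown instrument in row(s): ", paste(bad, collapse = ", "))
  for (instr in unique(items$instrument)) {
    info <- .instrumentInfo(instr)
    sel <- items$instrument == instr
    badItem <- which(sel & (items$item < 1 | items$item > info$nItems))
    if (length(badItem))
      stop(instr, " item index out of range in row(s): ",
           paste(badItem, collapse = ", "))
    lo <- info$firstCat; hi <- info$firstCat + info$nCats - 1L
    badResp <- which(sel & (items$response < lo | items$response > hi))
    if (length(badResp))
      stop(instr, " response out of range [", lo, ", ", hi, "] in row(s): ",
           paste(badResp, collapse = ", "))
  }
  key <- paste(items$participant_id, items$instrument, items$item)
  if (anyDuplicated(key))
    stop("duplicated (participant, instrument, item) in row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  items
}

#' Read and write laterality tables
#'
#' Long CSV format: `participant_id`, `lesion_side`, `trial`,
#' `pair_index`, `m1lat` (full precision).
#'
#' @param records a [LateralityRecord] or list of them (or a prebuilt
#'   table from [lateralityTable()]).
#' @param path CSV file path.
#' @export
writeLaterality <- function(records, path) {
  tab <- if (is.data.frame(records)) records else lateralityTable(records)
  tab$m1lat <- sprintf("%.17g", tab$m1lat)
  .atomicWrite(path, function(f)
    write.csv(tab, f, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname writeLaterality
#' @return `readLaterality()`: the long table with numeric `m1lat`.
#' @export
readLaterality <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$m1lat <- as.numeric(tab$m1lat)
  tab
}

#' Long laterality table to SEM-ready array
#'
#' @param tab table from [readLaterality()] / [lateralityTable()].
#' @return array `participants x trials x 8`, participant order
#'   `sort(unique(participant_id))`.
#' @export
lateralityArray <- function(tab) {
  ids <- sort(unique(tab$participant_id))
  nt <- max(tab$trial)
  arr <- array(NA_real_, c(length(ids), nt, 8))
  for (r in seq_len(nrow(tab)))
    arr[match(tab$participant_id[r], ids), tab$trial[r], tab$pair_index[r]] <-
      tab$m1lat[r]
  dimnames(arr) <- list(ids, NULL, paste0("pair_", 1:8))
  arr
}
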