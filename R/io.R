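## Format adapters: long CSV (+ JSON sidecar) and minimal EDF, plus input
## validation against the acquisition protocol.

#' Write / read a recording as long CSV with a JSON sidecar
#'
#' The CSV has columns `time_s`, `channel`, `value`; subject, state,
#' modality, rate and start time live in a `<path>.json` sidecar.
#'
#' @param rec a [Recording-class].
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `writeRecordingCSV` returns `path` invisibly; `readRecordingCSV`
#'   returns a [Recording-class].
#' @export
writeRecordingCSV <- function(rec, path) {
  n <- ncol(rec@samples)
  tab <- data.frame(
    time_s = rep(rec@startTime + (seq_len(n) - 1) / rec@rate,
                 times = nrow(rec@samples)),
    channel = rep(rec@channelLabels, each = n),
    value = as.vector(t(rec@samples)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = rec@subjectId, state = rec@state,
                            modality = rec@modality, rate = rec@rate,
                            start_time = rec@startTime),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRecordingCSV
#' @param sidecar sidecar JSON path (default `paste0(path, ".json")`).
#' @export
readRecordingCSV <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  channels <- unique(tab$channel)
  samples <- do.call(rbind, lapply(channels, function(ch)
    tab$value[tab$channel == ch]))
  Recording(meta$subject_id, meta$state, meta$modality, meta$rate, samples,
            channelLabels = channels, startTime = meta$start_time)
}

## ---- Minimal EDF (European Data Format) support ---------------------------
## Continuous EDF with 1-s data records and 16-bit samples. Implemented by
## hand because no installed R package reads or writes EDF; covers the
## plain-EDF subset this pipeline produces and consumes.

.padField <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write / read a recording as EDF
#'
#' Plain continuous EDF: one data record per second, one signal per
#' channel, 16-bit samples scaled to each channel's physical range.
#' Subject id and state are stored in the patient and recording
#' identification fields. Quantization limits round-trip fidelity to about
#' 1/65536 of the physical range.
#'
#' @param rec a [Recording-class] whose duration is a whole number of
#'   seconds.
#' @param path output `.edf` path.
#' @return `writeEDF` returns `path` invisibly; `readEDF` a
#'   [Recording-class].
#' @export
writeEDF <- function(rec, path) {
  nRec <- floor(durationS(rec))
  if (nRec < 1) stop("recording must span at least 1 s", call. = FALSE)
  spr <- round(rec@rate)  # samples per 1-s record
  ns <- nrow(rec@samples)
  x <- rec@samples[, seq_len(nRec * spr), drop = FALSE]
  ## 6 significant digits so the header fields represent the scale exactly
  physMax <- signif(pmax(apply(abs(x), 1L, max), 1e-6), 6)
  dig <- vapply(seq_len(ns), function(i)
    as.integer(round(x[i, ] / physMax[i] * 32767)), integer(ncol(x)))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .padField("0", 8L),
    .padField(rec@subjectId, 80L),
    .padField(paste(rec@state, rec@modality), 80L),
    "01.01.26", "00.00.00",
    .padField(256L * (1L + ns), 8L),
    .padField("", 44L),
    .padField(nRec, 8L),
    .padField(1L, 8L),
    .padField(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(rec@channelLabels, .padField, "", 16L), collapse = ""),
    paste(rep(.padField("", 80L), ns), collapse = ""),
    paste(rep(.padField("uV", 8L), ns), collapse = ""),
    paste(vapply(-physMax, function(v) .padField(sprintf("%.6g", v), 8L), ""),
          collapse = ""),
    paste(vapply(physMax, function(v) .padField(sprintf("%.6g", v), 8L), ""),
          collapse = ""),
    paste(rep(.padField(-32767L, 8L), ns), collapse = ""),  # symmetric range
    paste(rep(.padField(32767L, 8L), ns), collapse = ""),
    paste(rep(.padField("BP 0.5-30 Hz", 80L), ns), collapse = ""),
    paste(rep(.padField(spr, 8L), ns), collapse = ""),
    paste(rep(.padField("", 32L), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  for (r in seq_len(nRec)) {
    idx <- (r - 1L) * spr + seq_len(spr)
    for (i in seq_len(ns))
      writeBin(dig[idx, i], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname writeEDF
#' @param subjectId,state optional overrides for the identification fields.
#' @export
readEDF <- function(path, subjectId = NULL, state = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8L)
  patient <- rd(80L)
  recording <- rd(80L)
  rd(8L); rd(8L)                      # date, time
  rd(8L); rd(44L)                     # header bytes, reserved
  nRec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16L); fields(80L); fields(8L)
  physMin <- as.numeric(fields(8L)); physMax <- as.numeric(fields(8L))
  digMin <- as.numeric(fields(8L)); digMax <- as.numeric(fields(8L))
  fields(80L)
  spr <- as.integer(fields(8L)); fields(32L)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal rates are not supported", call. = FALSE)
  raw <- array(NA_real_, dim = c(spr[1L] * nRec, ns))
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, endian = "little")
      raw[(r - 1L) * spr[i] + seq_len(spr[i]), i] <-
        physMin[i] + (v - digMin[i]) / (digMax[i] - digMin[i]) *
          (physMax[i] - physMin[i])
    }
  }
  meta <- strsplit(recording, " +")[[1L]]
  Recording(subjectId %||% patient,
            state %||% meta[1L],
            if (ns == 1L) "ECG" else "EEG",
            spr[1L] / recDur, t(raw), channelLabels = labels, startTime = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate input recordings against the acquisition protocol
#'
#' Checks each file's sampling rate (500 Hz expected for EEG, 250 Hz for
#' ECG; others warned), EEG channel labels against the montage (a missing
#' montage channel is a hard failure), and duration (>= `minDurationS`
#' expected; shorter recordings are warned with the shortfall).
#'
#' @param paths character vector of `.edf` or `.csv` recording paths.
#' @param montage expected EEG channel labels.
#' @param minDurationS expected minimum duration (default 600 s).
#' @return data.frame with columns `file`, `level` (`pass`/`warn`/`fail`)
#'   and `message`, one or more rows per file.
#' @export
validateInputs <- function(paths, montage = eegMontage(), minDurationS = 600) {
  rows <- list()
  note <- function(file, level, message)
    rows[[length(rows) + 1L]] <<- data.frame(file = file, level = level,
                                             message = message)
  for (p in paths) {
    nBefore <- length(rows)
    rec <- suppressWarnings(tryCatch(
      if (grepl("\\.edf$", p, ignore.case = TRUE)) readEDF(p)
      else readRecordingCSV(p),
      error = function(e) e))
    if (inherits(rec, "error")) {
      note(p, "fail", sprintf("unreadable: %s", conditionMessage(rec)))
      next
    }
    expected <- if (rec@modality == "EEG") 500 else 250
    if (rec@rate != expected)
      note(p, "warn", sprintf("%s rate %g Hz (expected %g Hz)",
                              rec@modality, rec@rate, expected))
    if (rec@modality == "EEG") {
      missing <- setdiff(montage, rec@channelLabels)
      if (length(missing))
        note(p, "fail", sprintf("missing montage channel(s): %s",
                                paste(missing, collapse = ", ")))
    }
    dur <- durationS(rec)
    if (dur < minDurationS)
      note(p, "warn", sprintf("duration %.1f s is %.1f s short of %g s",
                              dur, minDurationS - dur, minDurationS))
    if (length(rows) == nBefore) note(p, "pass", "ok")
  }
  do.call(rbind, rows)
}
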