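# File I/O: PCM16 WAV for stimuli, a minimal EDF writer/reader for
# continuous multichannel recordings, and CSV/JSON result writers.

#' Write a stimulus as a 16-bit PCM WAV file
#'
#' @param wave a [synthesize_trial()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  x <- pmax(pmin(wave$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(wave$rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(wave$rate_hz * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(nbytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer for continuous recordings: one-second
#' data records, 16-bit samples, per-channel physical scaling from the data
#' range. Trailing samples beyond the last whole second are dropped. The
#' montage geometry and trial onsets are not part of EDF; pair the file with
#' the cohort metadata CSV / config written by [write_results()].
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  rate <- as.integer(rec$rate_hz)
  ns <- ncol(rec$data)
  n_rec <- floor(nrow(rec$data) / rate)
  stopifnot(n_rec >= 1)
  data <- rec$data[seq_len(n_rec * rate), , drop = FALSE]
  pmin_ <- apply(data, 2, min)
  pmax_ <- apply(data, 2, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)
  dmin <- -32768
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$meta$subject_id %||% "X", 80),
    pad_field("synthetic EEG", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(rec$montage$labels %||% sprintf("E%03d", seq_len(ns)),
                 pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", pmin_), pad_field, "", width = 8),
          collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), pad_field, "", width = 8),
          collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("BP 0.5-15Hz", 80), ns), collapse = ""),
    paste(rep(pad_field(rate, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(sig, con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- seq((r - 1) * rate + 1, r * rate)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round((data[rows, ch] - pmin_[ch]) * scale[ch] +
                                dmin))
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the subset of EDF that [write_edf()] produces (uniform sampling
#' rate, one-second records). Returns an `eeg_recording` without montage
#' geometry or trial onsets (labels only).
#'
#' @param path EDF file path.
#' @return an `eeg_recording` (montage `NULL`, labels in
#'   `attr(, "labels")`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); subj <- rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  stopifnot(length(unique(spr)) == 1, rec_dur == 1)
  rate <- spr[1]
  data <- matrix(0, n_rec * rate, ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = rate, size = 2, endian = "little")
      data[seq((r - 1) * rate + 1, r * rate), ch] <-
        pmin_[ch] + (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) /
          (dmax[ch] - dmin[ch])
    }
  }
  out <- structure(list(data = data, rate_hz = rate, montage = NULL,
                        trial_onsets = integer(), trial_samples = 0L,
                        meta = list(subject_id = subj)),
                   class = "eeg_recording")
  attr(out, "labels") <- labels
  out
}

#' Write an event grid as JSON
#' @param grid an [event_grid()]. @param path output path.
#' @return `path`, invisibly.
#' @export
write_event_grid_json <- function(grid, path) {
  jsonlite::write_json(unclass(grid), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an envelope spectrum as CSV (freq_hz, amplitude)
#' @param spectrum an [envelope_spectrum()]. @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(data.frame(freq_hz = spectrum$freqs_hz,
                       amplitude = spectrum$amplitude),
            path, row.names = FALSE)
  invisible(path)
}
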