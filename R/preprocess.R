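# Preprocessing chain: broad zero-phase band-pass, resampling, spatial
# down-sampling to a common montage, outer-ring exclusion, average
# re-reference, epoching with a pluggable artifact-rejection hook.

#' Band-pass filter specification
#'
#' Two-pass (zero-phase) Hamming-window FIR, order = three cycles of the low
#' cutoff (i.e. `3 * rate / low_hz` taps).
#'
#' @param low_hz,high_hz band edges in Hz.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 15) {
  stopifnot(low_hz > 0, low_hz < high_hz)
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "filter_spec")
}

#' Zero-phase band-pass filter a recording
#'
#' Applies the FIR band-pass forward and backward (via its squared-magnitude
#' frequency response), giving zero net phase shift.
#'
#' @param rec an `eeg_recording`.
#' @param spec a [filter_spec()].
#' @return the filtered recording.
#' @export
bandpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (spec$high_hz >= rec$rate_hz / 2) stop("band exceeds Nyquist")
  h <- design_bandpass(spec$low_hz, spec$high_hz, rec$rate_hz)
  min_len <- 3 * length(h)
  if (nrow(rec$data) < min_len) {
    stop(sprintf(
      "data too short for band-pass: %d samples, need at least %d (3 x filter order = 3 x %d taps)",
      nrow(rec$data), min_len, length(h)))
  }
  rec$data <- fir_filtfilt_fft(rec$data, h)
  rec
}

#' Resample a recording (downsampling only)
#'
#' FFT-based trigonometric resampling; exact for signals band-limited below
#' the target Nyquist frequency (guaranteed by the preceding band-pass).
#' Duration is preserved to within one sample and trial onsets are rescaled.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz target sampling rate, below the current rate.
#' @return the resampled recording.
#' @export
downsample <- function(rec, target_hz = 512) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_hz >= rec$rate_hz) {
    stop("upsampling not supported; target_hz must be below the current rate")
  }
  n <- nrow(rec$data)
  m <- round(n * target_hz / rec$rate_hz)
  rec$data <- fft_resample(rec$data, m)
  rec$trial_onsets <- round((rec$trial_onsets - 1) * target_hz /
                              rec$rate_hz) + 1
  rec$trial_samples <- round(rec$trial_samples * target_hz / rec$rate_hz)
  rec$rate_hz <- target_hz
  rec
}

#' Spatially downsample to a target montage
#'
#' Each target electrode is an inverse-distance-weighted average of the 4
#' nearest source electrodes (angular distance); an exactly coincident
#' source electrode is copied. Constant-preserving by construction.
#'
#' @param rec an `eeg_recording`.
#' @param target target `eeg_montage`.
#' @param k number of nearest source electrodes.
#' @return recording on the target montage.
#' @export
spatial_downsample <- function(rec, target, k = 4) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(target, "eeg_montage"))
  src <- rec$montage
  if (length(src$labels) < length(target$labels)) {
    stop("source montage has fewer electrodes than target")
  }
  ang <- angular_distance(target$pos, src$pos)  # n_tgt x n_src
  if (any(apply(ang, 1, min) > 2 * src$neighbor_thr)) {
    stop("disjoint layouts: some target electrode has no nearby source electrode")
  }
  n_tgt <- nrow(ang)
  W <- matrix(0, ncol(ang), n_tgt)
  for (j in seq_len(n_tgt)) {
    ord <- order(ang[j, ])[seq_len(k)]
    d <- ang[j, ord]
    if (d[1] < 1e-6) {
      W[ord[1], j] <- 1
    } else {
      wt <- 1 / d
      W[ord, j] <- wt / sum(wt)
    }
  }
  rec$data <- rec$data %*% W
  rec$montage <- target
  rec
}

#' Drop outer-ring electrodes
#'
#' @param rec an `eeg_recording` whose montage flags an outer ring.
#' @return recording restricted to non-ring electrodes.
#' @export
drop_outer_ring <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ring <- rec$montage$outer_ring
  if (is.null(ring)) stop("montage does not annotate an outer ring")
  keep <- which(!ring)
  rec$data <- rec$data[, keep, drop = FALSE]
  rec$montage <- montage_subset(rec$montage, keep)
  rec
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across electrodes from every channel;
#' idempotent (a projection).
#'
#' @param rec an `eeg_recording` with at least two electrodes.
#' @return the re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$data) < 2) stop("average reference needs >= 2 electrodes")
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Epoch a recording into trials
#'
#' Half-open windows `[onset, onset + trial_samples)`.
#'
#' @param rec an `eeg_recording`.
#' @param keep optional integer vector of trial indices to keep.
#' @return object of class `eeg_epochs`: `trials` array (samples x
#'   electrodes x trials), `rate_hz`, `montage`, `meta`, `kept`.
#' @export
epoch_recording <- function(rec, keep = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  on <- rec$trial_onsets
  len <- rec$trial_samples
  if (!length(on)) stop("recording has no trial onsets")
  if (any(on < 1) || any(on + len - 1 > nrow(rec$data))) {
    stop("trial windows fall outside the data")
  }
  if (is.null(keep)) keep <- seq_along(on)
  arr <- vapply(on[keep], function(o) {
    rec$data[seq(o, o + len - 1), , drop = FALSE]
  }, matrix(0, len, ncol(rec$data)))
  structure(list(trials = arr, rate_hz = rec$rate_hz,
                 montage = rec$montage, meta = rec$meta, kept = keep),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("EEG epochs: %d trials x %d channels x %d samples (%g Hz)\n",
              d[3], d[2], d[1], x$rate_hz))
  invisible(x)
}

#' Amplitude-threshold artifact rejection hook
#'
#' Default trial rejector: a trial is kept when no sample in any channel
#' exceeds `thresh_uv` microvolts in absolute value. The full APICE-style
#' artifact pipeline is out of scope; [preprocess()] accepts any function of
#' the same signature in its place.
#'
#' @param rec an `eeg_recording`.
#' @param thresh_uv rejection threshold in microvolts.
#' @return integer vector of retained trial indices.
#' @export
amplitude_artifact_reject <- function(rec, thresh_uv = 500) {
  on <- rec$trial_onsets
  len <- rec$trial_samples
  keep <- vapply(on, function(o) {
    max(abs(rec$data[seq(o, o + len - 1), ])) <= thresh_uv
  }, logical(1))
  which(keep)
}

#' Run the standard preprocessing chain
#'
#' Band-pass, downsample, optional spatial downsample to a common 64-channel
#' montage, outer-ring exclusion, average re-reference, artifact hook.
#'
#' @param rec an `eeg_recording`.
#' @param spec [filter_spec()].
#' @param target_hz analysis sampling rate.
#' @param target_montage montage to spatially downsample to when the source
#'   has more electrodes (`NULL` to skip).
#' @param artifact_hook function `rec -> integer trial indices` (or `NULL`).
#' @return list with `rec` (preprocessed recording) and `keep` (retained
#'   trial indices).
#' @export
preprocess <- function(rec, spec = filter_spec(), target_hz = 512,
                       target_montage = NULL,
                       artifact_hook = amplitude_artifact_reject) {
  rec <- bandpass(rec, spec)
  if (target_hz < rec$rate_hz) rec <- downsample(rec, target_hz)
  if (!is.null(target_montage) &&
      length(rec$montage$labels) > length(target_montage$labels)) {
    rec <- spatial_downsample(rec, target_montage)
  }
  rec <- drop_outer_ring(rec)
  rec <- rereference_average(rec)
  keep <- if (is.null(artifact_hook)) seq_along(rec$trial_onsets) else
    artifact_hook(rec)
  list(rec = rec, keep = keep)
}
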