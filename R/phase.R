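# The complex synchronization index (SI) between narrow-band EEG phase and
# the phase of stimulus-aligned reference sinusoids.
#
# SI = 1/(I*N) * sum_i sum_t exp(j * |phi_EEG(t,i) - phi_sin(t,i)|)
#
# with the phase difference wrapped to (-pi, pi] before the absolute value
# ("absolute" variant; the printed form, chance magnitude 2/pi) or used
# signed ("signed" variant; the conventional phase-locking value, chance
# magnitude -> 0). |SI| measures coupling strength; Arg(SI) the preferred
# phase.

#' Reference sinusoid phase series
#'
#' Phase of a cosine at `freq_hz` whose peak (phase 0) is aligned with the
#' event onsets at the start of the trial: `phase(t) = wrap(2*pi*f*t)`.
#'
#' @param freq_hz frequency in Hz. When `grid` is given the frequency must
#'   be one of the grid's beat/duple/triple frequencies (cycles spanning 1,
#'   2 or 3 grid steps) unless `check_commensurate = FALSE`.
#' @param duration_s duration of the series in seconds.
#' @param rate_hz sampling rate.
#' @param grid optional [event_grid()] used to validate commensurability.
#' @param check_commensurate validate `freq_hz` against the grid.
#' @return numeric vector of phases in (-pi, pi].
#' @examples
#' g <- event_grid()
#' ph <- reference_sinusoid(grid_frequencies(g)[["beat"]], 1.8, 1000, g)
#' ph[1 + 0.3 * 1000]  # phase 0 at the 300 ms grid point
#' @export
reference_sinusoid <- function(freq_hz, duration_s, rate_hz, grid = NULL,
                               check_commensurate = TRUE) {
  stopifnot(freq_hz > 0, duration_s > 0, rate_hz > 0)
  if (!is.null(grid) && check_commensurate) {
    fr <- grid_frequencies(grid)
    if (min(abs(fr - freq_hz)) > 1e-6 * freq_hz) {
      stop("frequency not commensurate with the event grid (expected one of ",
           paste(sprintf("%.4f", fr), collapse = ", "), " Hz)")
    }
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  wrap_phase(2 * pi * freq_hz * t)
}

#' Instantaneous phase of a narrow-band component
#'
#' Zero-phase FIR narrow-band filtering (Hamming window, order
#' `3 * rate / bw`, applied forward-backward) followed by the Hilbert
#' transform; returns the instantaneous phase of the analytic signal.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param center_hz band center frequency.
#' @param rate_hz sampling rate.
#' @param bw_hz filter bandwidth (full width), default 0.2 Hz.
#' @return phases in (-pi, pi], same shape as `x`.
#' @export
narrowband_phase <- function(x, center_hz, rate_hz, bw_hz = 0.2) {
  if (bw_hz >= center_hz) stop("bandwidth must be below the center frequency")
  h <- design_narrowband(center_hz, bw_hz, rate_hz)
  z <- fir_filtfilt_fft(x, h, analytic = TRUE)
  Arg(z)
}

#' Trim trial edges from a phase series
#'
#' Removes `trim_s` seconds from the beginning and end (where filter edge
#' effects concentrate).
#'
#' @param phase numeric vector or matrix (samples in rows).
#' @param rate_hz sampling rate.
#' @param trim_s seconds trimmed from each end (default 2).
#' @return the trimmed series.
#' @export
trim_edges <- function(phase, rate_hz, trim_s = 2) {
  n <- if (is.null(dim(phase))) length(phase) else nrow(phase)
  k <- round(trim_s * rate_hz)
  if (n <= 2 * k) stop("trial too short to trim ", trim_s, " s from each end")
  idx <- seq(k + 1, n - k)
  if (is.null(dim(phase))) phase[idx] else phase[idx, , drop = FALSE]
}

# Normalize (eeg_phases, ref_phases) into a list of wrapped phase-difference
# matrices, one per trial (samples x electrodes).
phase_diff_list <- function(eeg_phases, ref_phases) {
  if (!is.list(eeg_phases)) eeg_phases <- list(eeg_phases)
  if (!is.list(ref_phases)) ref_phases <- list(ref_phases)
  if (length(ref_phases) == 1 && length(eeg_phases) > 1) {
    ref_phases <- rep(ref_phases, length(eeg_phases))
  }
  if (length(eeg_phases) != length(ref_phases)) {
    stop("mismatched trial counts between EEG and reference phases")
  }
  mapply(function(e, r) {
    e <- as.matrix(e)
    if (nrow(e) != length(r)) {
      stop("mismatched sample counts between EEG and reference phases")
    }
    wrap_phase(e - r)
  }, eeg_phases, ref_phases, SIMPLIFY = FALSE)
}

# SI per electrode from a list of phase-difference matrices.
si_from_diffs <- function(dlist, variant = c("absolute", "signed")) {
  variant <- match.arg(variant)
  acc <- 0
  ntot <- 0
  for (d in dlist) {
    if (variant == "absolute") {
      acc <- acc + colSums(cos(d)) + 1i * colSums(abs(sin(d)))
    } else {
      acc <- acc + colSums(cos(d)) + 1i * colSums(sin(d))
    }
    ntot <- ntot + nrow(d)
  }
  acc / ntot
}

#' Complex synchronization index
#'
#' Averages unit vectors of the (wrapped) phase difference between EEG and
#' reference over samples and trials, per electrode. `variant = "absolute"`
#' takes the absolute value of the wrapped difference before the complex
#' exponential (angles restricted to `[0, pi]`, chance-level magnitude
#' `2/pi`); `variant = "signed"` uses the signed difference (the standard
#' phase-locking value, chance magnitude near 0; its angle is the preferred
#' phase used by the circular analyses).
#'
#' @param eeg_phases matrix (samples x electrodes) or list of such matrices,
#'   one per trial.
#' @param ref_phases numeric vector (or list, one per trial) of reference
#'   phases; a single vector is recycled across trials.
#' @param variant `"absolute"` (default) or `"signed"`.
#' @return complex vector, one SI per electrode, with attributes `n_trials`,
#'   `n_samples` (per trial), `variant`.
#' @examples
#' ph <- runif(1000, -pi, pi)
#' synchronization_index(cbind(ph), ph)  # identical phases: SI = 1+0i
#' @export
synchronization_index <- function(eeg_phases, ref_phases,
                                  variant = c("absolute", "signed")) {
  variant <- match.arg(variant)
  dlist <- phase_diff_list(eeg_phases, ref_phases)
  si <- si_from_diffs(dlist, variant)
  structure(si, n_trials = length(dlist), n_samples = nrow(dlist[[1]]),
            variant = variant)
}

#' Subject-level SI map
#'
#' Computes the complex SI at each electrode for each requested frequency.
#' The recording is narrow-band filtered as a continuous signal (trials are
#' contiguous, so no within-trial filter edges are introduced), the
#' instantaneous phase is epoched into trials, `trim_s` seconds are removed
#' from each trial edge, and the SI against the stimulus-aligned reference
#' sinusoid is averaged over samples and trials.
#'
#' Frequencies matching the grid's beat/duple/triple hierarchy are validated
#' as commensurate; any other value (e.g. the 1.389/2.500/3.055 Hz control
#' frequencies) is accepted as an arbitrary target.
#'
#' @param rec a preprocessed `eeg_recording` with trial onsets.
#' @param grid the [event_grid()] the stimulus was built from.
#' @param freqs_hz numeric vector of target frequencies.
#' @param variant `"absolute"` or `"signed"` (see
#'   [synchronization_index()]).
#' @param bw_hz narrow-band filter bandwidth.
#' @param trim_s seconds trimmed from each trial edge.
#' @param keep trial indices to retain (default all).
#' @return object of class `sync_result`: complex matrix `si` (electrodes x
#'   frequencies), plus `freqs_hz`, `variant`, `n_trials`, `n_samples`,
#'   `montage`, `meta`.
#' @export
si_map <- function(rec, grid, freqs_hz, variant = c("absolute", "signed"),
                   bw_hz = 0.2, trim_s = 2, keep = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(keep)) keep <- seq_along(rec$trial_onsets)
  if (!length(keep)) stop("no trials to analyze")
  si <- matrix(NA_complex_, ncol(rec$data), length(freqs_hz),
               dimnames = list(rec$montage$labels, NULL))
  ns <- NA_integer_
  for (j in seq_along(freqs_hz)) {
    dl <- subject_phase_diffs(rec, grid, freqs_hz[j], bw_hz, trim_s, keep)
    si[, j] <- si_from_diffs(dl, variant)
    ns <- nrow(dl[[1]])
  }
  structure(list(si = si, freqs_hz = freqs_hz, variant = variant,
                 n_trials = length(keep), n_samples = ns,
                 montage = rec$montage, meta = rec$meta),
            class = "sync_result")
}

# Phase-difference matrices (one per kept trial) for one target frequency.
subject_phase_diffs <- function(rec, grid, freq_hz, bw_hz = 0.2, trim_s = 2,
                                keep = NULL) {
  if (is.null(keep)) keep <- seq_along(rec$trial_onsets)
  rate <- rec$rate_hz
  ph <- narrowband_phase(rec$data, freq_hz, rate, bw_hz)
  len <- rec$trial_samples
  k <- round(trim_s * rate)
  if (len <= 2 * k) stop("trials too short for the requested edge trim")
  rel <- seq(k, len - k - 1)             # 0-based within-trial offsets
  ref <- wrap_phase(2 * pi * freq_hz * rel / rate)
  lapply(rec$trial_onsets[keep], function(o) {
    wrap_phase(ph[o + rel, , drop = FALSE] - ref)
  })
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("SI map (%s variant): %d electrodes x %d frequencies, %d trials x %d samples\n",
              x$variant, nrow(x$si), ncol(x$si), x$n_trials, x$n_samples))
  top <- apply(Mod(x$si), 2, max)
  cat("  max |SI| per frequency:",
      paste(sprintf("%.2f Hz: %.3f", x$freqs_hz, top), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.sync_result <- function(x, ...) {
  data.frame(
    subject_id = x$meta$subject_id %||% NA_character_,
    electrode = rep(rownames(x$si), ncol(x$si)),
    frequency_hz = rep(x$freqs_hz, each = nrow(x$si)),
    si_real = as.vector(Re(x$si)),
    si_imag = as.vector(Im(x$si)),
    si_abs = as.vector(Mod(x$si)),
    si_angle = as.vector(Arg(x$si)),
    n_trials = x$n_trials,
    variant = x$variant,
    stringsAsFactors = FALSE
  )
}
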