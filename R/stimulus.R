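# Stimulus construction: the metrically ambiguous six-event rhythm on a
# 300 ms grid (tone, rest, tone, tone, tone, rest), audio synthesis, and the
# envelope spectrum whose peaks tag the beat and meter frequencies.

#' Default six-event rhythmic pattern
#'
#' Tone, rest, tone, tone, tone, rest on a 300 ms grid. This pattern is
#' metrically ambiguous: it supports both a duple (groups of two beats) and a
#' triple (groups of three beats) reading.
#' @export
default_pattern <- c("tone", "rest", "tone", "tone", "tone", "rest")

parse_pattern <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1 &&
      !pattern %in% c("tone", "rest")) {
    pattern <- strsplit(toupper(pattern), "")[[1]]
    pattern <- c(T = "tone", R = "rest")[pattern]
    if (anyNA(pattern)) stop("pattern string may contain only 'T' and 'R'")
    names(pattern) <- NULL
  }
  if (!length(pattern)) stop("pattern must be nonempty")
  if (!all(pattern %in% c("tone", "rest"))) {
    stop("unknown event kind in pattern; use 'tone' or 'rest'")
  }
  pattern
}

#' Build the rhythmic event grid
#'
#' Lays the event pattern out on an isochronous grid and derives the cycle
#' duration, tone onset times and the beat/meter frequencies (1/step,
#' 1/(2*step), 1/(3*step)).
#'
#' @param pattern character vector of `"tone"`/`"rest"` entries, or a compact
#'   string such as `"TRTTTR"`.
#' @param grid_step_ms grid step (event onset-to-onset) in milliseconds.
#' @param n_repeats number of pattern repetitions per trial.
#' @return an object of class `event_grid` with fields `pattern`,
#'   `grid_step_ms`, `cycle_ms`, `tone_onsets_ms`, `n_repeats`.
#' @examples
#' g <- event_grid()
#' g$cycle_ms            # 1800
#' g$tone_onsets_ms      # 0 600 900 1200
#' trial_duration_s(g)   # 36
#' @export
event_grid <- function(pattern = default_pattern, grid_step_ms = 300,
                       n_repeats = 20) {
  pattern <- parse_pattern(pattern)
  stopifnot(grid_step_ms > 0, n_repeats >= 1)
  onsets <- (which(pattern == "tone") - 1) * grid_step_ms
  g <- structure(list(
    pattern = pattern,
    grid_step_ms = grid_step_ms,
    cycle_ms = length(pattern) * grid_step_ms,
    tone_onsets_ms = onsets,
    n_repeats = as.integer(n_repeats)
  ), class = "event_grid")
  g
}

#' @export
print.event_grid <- function(x, ...) {
  cat("Event grid:", paste(ifelse(x$pattern == "tone", "T", "R"),
                           collapse = ""),
      sprintf("(%g ms step, cycle %g ms, %d repeats, trial %g s)\n",
              x$grid_step_ms, x$cycle_ms, x$n_repeats, trial_duration_s(x)))
  invisible(x)
}

#' Trial duration in seconds
#' @param grid an [event_grid()].
#' @export
trial_duration_s <- function(grid) {
  grid$n_repeats * grid$cycle_ms / 1000
}

#' Beat and meter frequencies of a grid
#'
#' Exact rational frequencies of the metric hierarchy: one cycle per grid
#' step (beat), per two steps (duple meter) and per three steps (triple
#' meter). For the default 300 ms grid these are 10/3, 5/3 and 10/9 Hz
#' (displayed as 3.33, 1.67, 1.11).
#'
#' @param grid an [event_grid()].
#' @return named numeric vector `c(beat=, duple=, triple=)`.
#' @export
grid_frequencies <- function(grid) {
  step_s <- grid$grid_step_ms / 1000
  c(beat = 1 / step_s, duple = 1 / (2 * step_s), triple = 1 / (3 * step_s))
}

#' Synthesize one stimulus trial
#'
#' Places a tone at every tone onset of every cycle; silence elsewhere.
#' Tones are sinusoids with raised-cosine onset/offset ramps and, by default,
#' an exponential amplitude decay emulating the percussive timbres (piano,
#' vibraphone, guitar) used with this rhythm; `decay_ms = NULL` gives
#' sustained tones.
#'
#' @param grid an [event_grid()].
#' @param tone_freq_hz carrier pitch in Hz (default 440, note A).
#' @param rate_hz audio sampling rate; must be at least `4 * tone_freq_hz`.
#' @param tone_dur_ms tone duration; defaults to the full grid step.
#' @param ramp_ms raised-cosine ramp duration at each tone edge.
#' @param decay_ms exponential decay time constant of the tone amplitude, or
#'   `NULL` for no decay.
#' @return object of class `stimulus_wave`: list with `samples`, `rate_hz`,
#'   `tone_freq_hz`, `tone_dur_ms`, `grid`.
#' @examples
#' w <- synthesize_trial(event_grid(), rate_hz = 8000)
#' length(w$samples) / w$rate_hz   # 36 s
#' @export
synthesize_trial <- function(grid, tone_freq_hz = 440, rate_hz = 44100,
                             tone_dur_ms = grid$grid_step_ms, ramp_ms = 10,
                             decay_ms = 130) {
  stopifnot(inherits(grid, "event_grid"))
  if (rate_hz < 4 * tone_freq_hz) {
    stop("rate_hz must be at least 4 * tone_freq_hz")
  }
  n <- round(grid$n_repeats * grid$cycle_ms / 1000 * rate_hz)
  samples <- numeric(n)
  ns <- round(tone_dur_ms / 1000 * rate_hz)
  if (ns > 0 && length(grid$tone_onsets_ms)) {
    tt <- (seq_len(ns) - 1) / rate_hz
    env <- rep(1, ns)
    nr <- round(ramp_ms / 1000 * rate_hz)
    if (nr > 0) {
      r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      env[seq_len(nr)] <- env[seq_len(nr)] * r
      env[seq(ns, ns - nr + 1)] <- env[seq(ns, ns - nr + 1)] * r
    }
    if (!is.null(decay_ms)) env <- env * exp(-tt / (decay_ms / 1000))
    tone <- 0.9 * env * sin(2 * pi * tone_freq_hz * tt)
    onsets_s <- rep((0:(grid$n_repeats - 1)) * grid$cycle_ms, each =
                      length(grid$tone_onsets_ms)) + grid$tone_onsets_ms
    for (o in onsets_s) {
      i0 <- round(o / 1000 * rate_hz) + 1
      idx <- i0:min(i0 + ns - 1, n)
      samples[idx] <- samples[idx] + tone[seq_along(idx)]
    }
  }
  samples <- pmax(pmin(samples, 1), -1)
  structure(list(samples = samples, rate_hz = rate_hz,
                 tone_freq_hz = tone_freq_hz, tone_dur_ms = tone_dur_ms,
                 grid = grid),
            class = "stimulus_wave")
}

#' @export
print.stimulus_wave <- function(x, ...) {
  cat(sprintf("Stimulus wave: %.3f s at %g Hz, carrier %g Hz\n",
              length(x$samples) / x$rate_hz, x$rate_hz, x$tone_freq_hz))
  invisible(x)
}

#' Envelope spectrum of a stimulus
#'
#' Extracts the temporal envelope of the waveform with the Hilbert transform
#' (magnitude of the analytic signal), removes its mean, and computes the DFT
#' amplitude spectrum. Peaks are local maxima within `peak_range` whose
#' amplitude exceeds `thresh_factor` times the median in-range amplitude and
#' a small relative floor (2% of the in-range maximum, guarding against
#' numerically tiny ripple in noiseless synthetic input).
#'
#' @param wave a [synthesize_trial()] result, or a list with `samples` and
#'   `rate_hz`.
#' @param peak_range frequency range (Hz) searched for peaks.
#' @param thresh_factor multiple of the median in-range amplitude a local
#'   maximum must exceed.
#' @param max_freq_hz upper edge of the stored spectrum.
#' @return object of class `envelope_spectrum`: `freqs_hz`, `amplitude`,
#'   `peak_freqs_hz`, `peak_amps`, `resolution_hz`.
#' @examples
#' w <- synthesize_trial(event_grid(), rate_hz = 8000)
#' sp <- envelope_spectrum(w)
#' round(sp$peak_freqs_hz, 2)  # 0.56 1.11 1.67 2.22 2.78 3.33
#' @export
envelope_spectrum <- function(wave, peak_range = c(0.2, 5),
                              thresh_factor = 5, max_freq_hz = 30) {
  samples <- wave$samples
  rate <- wave$rate_hz
  n <- length(samples)
  res <- rate / n
  if (res > 0.06) {
    stop("input too short: frequency resolution ", signif(res, 3),
         " Hz exceeds 0.06 Hz (need >= ~17 s)")
  }
  env <- Mod(analytic_signal(samples))
  dc <- mean(env)
  env <- env - dc
  A <- Mod(stats::fft(env)) * 2 / n
  nk <- floor(n / 2) + 1
  freqs <- (seq_len(nk) - 1) * res
  keep <- freqs <= max_freq_hz
  freqs <- freqs[keep]
  A <- A[seq_len(nk)][keep]
  inr <- which(freqs >= peak_range[1] & freqs <= peak_range[2])
  # floors: 2% of the strongest in-range component (numerical ripple in
  # noiseless audio) and 1% of the envelope DC level (an unmodulated
  # carrier has no meaningful envelope peaks at all)
  thr <- max(thresh_factor * stats::median(A[inr]), 0.02 * max(A[inr]),
             0.01 * dc)
  pk <- inr[-c(1, length(inr))]
  pk <- pk[A[pk] > A[pk - 1] & A[pk] >= A[pk + 1] & A[pk] > thr]
  structure(list(freqs_hz = freqs, amplitude = A,
                 peak_freqs_hz = freqs[pk], peak_amps = A[pk],
                 resolution_hz = res),
            class = "envelope_spectrum")
}

#' Classify envelope-spectrum peaks against the metric hierarchy
#'
#' Maps detected peaks onto the rhythm's frequency landmarks: the
#' subharmonic (below 0.9 Hz), triple meter (0.9-1.4 Hz), duple meter
#' (1.4-2.0 Hz), the two superharmonics (2.0-3.0 Hz), and the beat - the
#' dominant (largest-amplitude) peak above 3 Hz. Percussive tone envelopes
#' also carry weak harmonics above the beat frequency (e.g. 3.89 Hz); the
#' beat is identified by dominance, not by being the fastest local maximum.
#'
#' @param spectrum an [envelope_spectrum()].
#' @return named numeric vector with entries `subharmonic`, `triple`,
#'   `duple`, `super1`, `super2`, `beat` (NA when absent).
#' @export
metric_peaks <- function(spectrum) {
  f <- spectrum$peak_freqs_hz
  a <- spectrum$peak_amps
  pick_range <- function(lo, hi, which_one = 1) {
    i <- which(f > lo & f < hi)
    if (length(i) >= which_one) f[i][order(f[i])][which_one] else NA_real_
  }
  hi <- which(f > 3 & f <= 5)
  beat <- if (length(hi)) f[hi][which.max(a[hi])] else NA_real_
  c(subharmonic = pick_range(0.2, 0.9),
    triple = pick_range(0.9, 1.4),
    duple = pick_range(1.4, 2.0),
    super1 = pick_range(2.0, 3.0, 1),
    super2 = pick_range(2.0, 3.0, 2),
    beat = beat)
}

#' @export
print.envelope_spectrum <- function(x, ...) {
  cat(sprintf("Envelope spectrum: %.4f Hz resolution; peaks at %s Hz\n",
              x$resolution_hz,
              paste(sprintf("%.2f", x$peak_freqs_hz), collapse = ", ")))
  invisible(x)
}

#' @export
plot.envelope_spectrum <- function(x, xlim = c(0, 5), ...) {
  keep <- x$freqs_hz <= xlim[2]
  plot(x$freqs_hz[keep], x$amplitude[keep], type = "l",
       xlab = "Frequency (Hz)", ylab = "Envelope amplitude (a.u.)", ...)
  points(x$peak_freqs_hz, x$peak_amps, col = 2, pch = 19)
  text(x$peak_freqs_hz, x$peak_amps, sprintf("%.2f", x$peak_freqs_hz),
       pos = 3, col = 2, cex = 0.8)
  invisible(x)
}
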