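# Synthetic preterm cohort generator. Stands in for non-shareable clinical
# recordings: multichannel EEG with oscillatory components phase-locked to
# the stimulus periodicities over a frontocentral profile, embedded in
# 1/f + white noise, with coupling strength a monotone function of
# gestational age (GA). The default effect structure encodes the
# developmental pattern the pipeline is designed to detect: beat coupling at
# all ages and increasing with GA; duple/triple coupling absent before
# 33 weeks GA and increasing after.

#' Generative configuration for the synthetic cohort
#'
#' Coupling amplitudes are in microvolts and are piecewise-linear in the
#' gestational age at recording: `base + slope * (ga - onset)` for
#' `ga >= onset`, zero below. Phase lags of the locked components are ~0
#' (sd `lag_jitter_sd` rad) for subjects at/after `ga_split` weeks and
#' uniform on the circle for younger subjects, emulating the age-related
#' concentration of the preferred coupling phase. Noise is 1/f^alpha plus
#' white noise.
#'
#' The `"full"` profile mirrors the acquisition protocol (1000 Hz, 54 trials
#' of 36 s); the `"desk"` profile keeps the identical effect structure at a
#' scale suited to interactive runs and continuous testing (256 Hz, 6
#' trials).
#'
#' @param profile `"desk"` or `"full"` (sets `rate_hz` and `n_trials`).
#' @param beat,duple,triple named numeric vectors `c(base=, slope=, onset=)`
#'   describing the coupling-vs-GA curves (microvolts, microvolts/week,
#'   weeks).
#' @param ga_split age split (weeks GA) for the phase-lag regime.
#' @param lag_jitter_sd phase-lag jitter (rad) for the older profile.
#' @param pink_sd,alpha 1/f noise standard deviation (microvolts) and
#'   spectral exponent.
#' @param white_sd white noise standard deviation (microvolts).
#' @param f_floor_hz 1/f shaping is flattened below this frequency.
#' @param n_trials trials per subject; `rate_hz` simulation sampling rate;
#'   `trial_start_s` silence before the first trial (also appended after the
#'   last, keeping filter edges away from trials).
#' @param spatial_sigma_rad width of the frontocentral profile.
#' @return list of class `generative_config`.
#' @export
generative_config <- function(profile = c("desk", "full"),
                              beat = c(base = 1.5, slope = 0.35, onset = 28),
                              duple = c(base = 0.8, slope = 1.0, onset = 33),
                              triple = c(base = 0.8, slope = 1.0, onset = 33),
                              ga_split = 33, lag_jitter_sd = 0.2,
                              pink_sd = 20, alpha = 1, white_sd = 5,
                              f_floor_hz = 0.1,
                              n_trials = NULL, rate_hz = NULL,
                              trial_start_s = 5,
                              spatial_sigma_rad = 0.8) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    desk = list(rate_hz = 256, n_trials = 6),
    full = list(rate_hz = 1000, n_trials = 54))
  cfg <- list(profile = profile,
              coupling = list(beat = beat, duple = duple, triple = triple),
              ga_split = ga_split, lag_jitter_sd = lag_jitter_sd,
              pink_sd = pink_sd, alpha = alpha, white_sd = white_sd,
              f_floor_hz = f_floor_hz,
              n_trials = n_trials %||% defaults$n_trials,
              rate_hz = rate_hz %||% defaults$rate_hz,
              trial_start_s = trial_start_s,
              spatial_sigma_rad = spatial_sigma_rad)
  stopifnot(cfg$alpha >= 0.5, cfg$alpha <= 2, cfg$n_trials >= 1,
            cfg$pink_sd >= 0, cfg$white_sd >= 0)
  class(cfg) <- "generative_config"
  cfg
}

# Coupling amplitude (microvolts) for one frequency band at a given GA.
coupling_amplitude <- function(cfg, ga, band) {
  p <- cfg$coupling[[band]]
  ifelse(ga >= p[["onset"]], pmax(0, p[["base"]] + p[["slope"]] *
                                    (ga - p[["onset"]])), 0)
}

# 1/f^alpha + white noise, one column per channel, via frequency-domain
# shaping. Each channel is normalized to the requested pink sd.
make_noise <- function(n, n_chan, rate_hz, cfg) {
  freqs <- seq(0, rate_hz / 2, by = rate_hz / n)
  shape <- pmax(freqs, cfg$f_floor_hz)^(-cfg$alpha / 2)
  shape[1] <- 0
  out <- matrix(0, n, n_chan)
  nk <- length(shape)
  for (ch in seq_len(n_chan)) {
    half <- complex(real = rnorm(nk), imaginary = rnorm(nk)) * shape
    spec <- numeric(n) + 0i
    spec[seq_len(nk)] <- half
    if (n %% 2 == 0) spec[nk] <- complex(real = Re(half[nk]))
    spec[seq(n, n - nk + 2)] <- Conj(spec[seq(2, nk)])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    pink <- if (cfg$pink_sd > 0) x / stats::sd(x) * cfg$pink_sd else 0
    out[, ch] <- pink + rnorm(n, sd = cfg$white_sd)
  }
  out
}

#' Simulate one subject's recording
#'
#' Produces `meta$seed`-reproducible multichannel data: stimulus-locked
#' cosines at the beat, duple and triple frequencies (amplitudes from the
#' coupling curves at the subject's GA, weighted by the frontocentral
#' profile, phase-lagged per the subject's regime) during the trial span,
#' plus 1/f and white noise everywhere.
#'
#' @param meta one row of a [cohort_meta()] table (or a list with
#'   `ga_record_weeks` and `seed`).
#' @param grid an [event_grid()].
#' @param cfg a [generative_config()].
#' @param montage an [make_montage()] result.
#' @return object of class `eeg_recording`: `data` (samples x electrodes
#'   matrix, microvolts), `rate_hz`, `montage`, `trial_onsets` (1-based
#'   sample indices), `trial_samples`, `meta` (including the drawn phase
#'   lags, for diagnostics).
#' @export
simulate_subject <- function(meta, grid, cfg = generative_config(),
                             montage = make_montage(64)) {
  meta <- as.list(meta)
  stopifnot(!is.null(meta$ga_record_weeks), !is.null(meta$seed))
  set.seed(meta$seed)
  rate <- cfg$rate_hz
  trial_s <- trial_duration_s(grid)
  stim_s <- cfg$n_trials * trial_s
  dur_s <- 2 * cfg$trial_start_s + stim_s
  n <- round(dur_s * rate)
  n_chan <- length(montage$labels)
  w <- frontocentral_profile(montage, sigma_rad = cfg$spatial_sigma_rad)

  ga <- meta$ga_record_weeks
  freqs <- grid_frequencies(grid)
  older <- ga >= cfg$ga_split
  lags <- vapply(names(freqs), function(b) {
    if (older) rnorm(1, 0, cfg$lag_jitter_sd) else runif(1, -pi, pi)
  }, numeric(1))

  data <- make_noise(n, n_chan, rate, cfg)
  i0 <- round(cfg$trial_start_s * rate)
  idx <- seq(i0 + 1, i0 + round(stim_s * rate))
  t_rel <- (seq_along(idx) - 1) / rate
  for (b in names(freqs)) {
    a <- coupling_amplitude(cfg, ga, b)
    if (a > 0) {
      comp <- a * cos(2 * pi * freqs[[b]] * t_rel + lags[[b]])
      data[idx, ] <- data[idx, ] + outer(comp, w)
    }
  }
  trial_onsets <- i0 + round((0:(cfg$n_trials - 1)) * trial_s * rate) + 1
  meta$lags <- lags
  structure(list(data = data, rate_hz = rate, montage = montage,
                 trial_onsets = trial_onsets,
                 trial_samples = round(trial_s * rate), meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s at %g Hz), %d trials\n",
              ncol(x$data), nrow(x$data), nrow(x$data) / x$rate_hz,
              x$rate_hz, length(x$trial_onsets)))
  invisible(x)
}

#' Cohort metadata table
#'
#' Gestational ages at recording are stratified: half the subjects (rounded
#' down) are spread uniformly below `ga_split`, the rest at or above it, so
#' that an `n = 46` cohort over 28-36 weeks yields the 23/23 median split at
#' 33 weeks. GA at birth is the recording age minus a ~8.5 day delay.
#' Per-subject simulation seeds are derived deterministically from `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param ga_range recording-age range in weeks GA.
#' @param seed cohort master seed.
#' @param ga_split grouping threshold (weeks GA at recording).
#' @return data.frame with columns `subject_id`, `ga_birth_weeks`,
#'   `ga_record_weeks`, `group` (`"younger"`/`"older"`), `seed`.
#' @export
cohort_meta <- function(n_subjects = 46, ga_range = c(28, 36), seed = 1,
                        ga_split = 33) {
  stopifnot(n_subjects >= 2)
  if (diff(ga_range) <= 0) stop("empty ga_range")
  set.seed(derive_seed(seed, 0))
  n_young <- floor(n_subjects / 2)
  n_old <- n_subjects - n_young
  grid_y <- ga_range[1] + (ga_split - ga_range[1]) *
    (seq_len(n_young) - 0.5) / n_young
  grid_o <- ga_split + (ga_range[2] - ga_split) *
    (seq_len(n_old) - 0.5) / n_old
  jit <- function(x, lo, hi) pmin(pmax(x + runif(length(x), -0.15, 0.15),
                                       lo), hi - 1e-6)
  ga_rec <- c(jit(grid_y, ga_range[1], ga_split),
              jit(grid_o, ga_split, ga_range[2] + 1e-6))
  delay <- pmin(pmax(rnorm(n_subjects, 8.5 / 7, 0.35), 0.3), 3)
  ga_birth <- pmin(pmax(ga_rec - delay, 27), 35)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    ga_birth_weeks = round(ga_birth, 2),
    ga_record_weeks = round(ga_rec, 2),
    group = ifelse(ga_rec >= ga_split, "older", "younger"),
    seed = vapply(seq_len(n_subjects), function(s) derive_seed(seed, s),
                  numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full cohort
#'
#' Convenience wrapper returning one [simulate_subject()] recording per row
#' of the metadata table. For large cohorts prefer iterating over
#' [cohort_meta()] rows to bound memory (this is what [run_pipeline()] does).
#'
#' @inheritParams cohort_meta
#' @param grid an [event_grid()].
#' @param cfg a [generative_config()].
#' @param montage an [make_montage()] result.
#' @return list with `meta` (data.frame) and `recordings` (list of
#'   `eeg_recording`).
#' @export
simulate_cohort <- function(n_subjects = 46, ga_range = c(28, 36),
                            cfg = generative_config(), seed = 1,
                            grid = event_grid(),
                            montage = make_montage(64)) {
  meta <- cohort_meta(n_subjects, ga_range, seed, cfg$ga_split)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    simulate_subject(meta[i, ], grid, cfg, montage)
  })
  list(meta = meta, recordings = recs)
}
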