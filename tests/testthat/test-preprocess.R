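# Preprocessing chain: band-pass, resampling, spatial downsampling,
# re-referencing, epoching.

make_rec <- function(data, rate, onsets = integer(), trial_samples = 0L,
                     montage = NULL) {
  structure(list(data = data, rate_hz = rate, montage = montage,
                 trial_onsets = onsets, trial_samples = trial_samples,
                 meta = list(subject_id = "T")),
            class = "eeg_recording")
}

test_that("band-pass preserves the passband and suppresses the stopbands", {
  rate <- 256
  n <- 60 * rate
  t <- (0:(n - 1)) / rate
  x <- cbind(sin(2 * pi * 1 * t), sin(2 * pi * 0.1 * t),
             sin(2 * pi * 30 * t), 0)
  rec <- bandpass(make_rec(x, rate))
  mid <- seq(10 * rate, 50 * rate)
  gain <- function(j) stats::sd(rec$data[mid, j]) / stats::sd(x[mid, j])
  expect_equal(gain(1), 1, tolerance = 0.01)
  expect_lt(gain(2), 0.1)                      # >= 10x attenuation at 0.1 Hz
  expect_lt(20 * log10(gain(3)), -20)          # >= 20 dB one octave above
  expect_true(all(rec$data[, 4] == 0))
  # zero net phase shift: cross-correlation peak at lag 0
  cc <- stats::ccf(rec$data[mid, 1], x[mid, 1], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(bandpass(make_rec(cbind(rnorm(100)), rate)), "too short")
})

test_that("resampling preserves durations, constants and tones", {
  rate <- 1000
  n <- 40 * rate
  t <- (0:(n - 1)) / rate
  x <- cbind(sin(2 * pi * 5 * t), 1)
  rec <- make_rec(x, rate, onsets = 2 * rate + 1, trial_samples = 36 * rate)
  rd <- downsample(rec, 512)
  expect_equal(nrow(rd$data), 40 * 512)
  expect_equal(rd$trial_samples, 18432)        # 36 s at 512 Hz
  expect_equal(rd$trial_onsets, 2 * 512 + 1)
  expect_equal(rd$data[, 2], rep(1, nrow(rd$data)), tolerance = 1e-9)
  X <- Mod(stats::fft(rd$data[, 1]))
  expect_equal((which.max(X[1:5000]) - 1) * 512 / nrow(rd$data), 5,
               tolerance = 1e-3)
  expect_error(downsample(rd, 1024), "upsampling")
})

test_that("spatial downsampling is identity on identical layouts and preserves constants", {
  m64 <- make_montage(64)
  m124 <- make_montage(124)
  x <- matrix(rnorm(50 * 64), 50, 64)
  rec <- make_rec(x, 100, montage = m64)
  expect_equal(spatial_downsample(rec, m64)$data, x, tolerance = 1e-12)

  const <- make_rec(matrix(3, 50, 124), 100, montage = m124)
  expect_equal(spatial_downsample(const, m64)$data,
               matrix(3, 50, 64), tolerance = 1e-12)
})

test_that("spatially smooth patterns survive 124 -> 64 downsampling", {
  m64 <- make_montage(64)
  m124 <- make_montage(124)
  src <- c(sin(0.9), 0.2, cos(0.9))
  pat <- function(m) exp(-(acos(pmin(1, m$pos %*% src)) / 0.7)^2)
  x124 <- outer(sin(2 * pi * 3 * (0:99) / 100), drop(pat(m124)))
  rec <- spatial_downsample(make_rec(x124, 100, montage = m124), m64)
  direct <- outer(sin(2 * pi * 3 * (0:99) / 100), drop(pat(m64)))
  expect_gt(cor(as.vector(rec$data), as.vector(direct)), 0.9)
})

test_that("average re-referencing is a zero-mean projection", {
  x <- matrix(rnorm(200 * 8), 200, 8)
  rec <- make_rec(x, 100)
  r1 <- rereference_average(rec)
  expect_lt(max(abs(rowMeans(r1$data))), 1e-10)
  r2 <- rereference_average(r1)
  expect_lt(max(abs(r1$data - r2$data)), 1e-10)

  a <- rnorm(100)
  pair <- make_rec(cbind(a, -a), 100)
  expect_equal(rereference_average(pair)$data, pair$data,
               tolerance = 1e-12)
  expect_error(rereference_average(make_rec(cbind(a), 100)), ">= 2")
})

test_that("epoching returns equal-length windows and flags bad trials", {
  rate <- 100
  rec <- make_rec(matrix(rnorm(1000 * 4), 1000, 4), rate,
                  onsets = c(1, 201, 401, 601), trial_samples = 200)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$trials), c(200, 4, 4))

  rec$data[450, 2] <- 600  # artifact in trial 3
  keep <- amplitude_artifact_reject(rec, thresh_uv = 500)
  expect_equal(keep, c(1, 2, 4))
  expect_equal(dim(epoch_recording(rec, keep)$trials)[3], 3)

  bad <- make_rec(matrix(0, 100, 2), rate, onsets = 50,
                  trial_samples = 200)
  expect_error(epoch_recording(bad), "outside")
})

test_that("the full chain preserves the phase of a frontocentral component", {
  g <- event_grid()
  cfg <- generative_config(beat = c(base = 5, slope = 0, onset = 20),
                           duple = c(base = 0, slope = 0, onset = 33),
                           triple = c(base = 0, slope = 0, onset = 33),
                           pink_sd = 0, white_sd = 0, n_trials = 2)
  meta <- list(subject_id = "C1", ga_record_weeks = 34, seed = 21)
  rec <- simulate_subject(meta, g, cfg, make_montage(64))
  rec$meta$lags  # older profile: jittered lag, known
  lag <- rec$meta$lags[["beat"]]
  pp <- preprocess(rec, target_hz = 128)
  e <- which.max(frontocentral_profile(pp$rec$montage))
  fb <- grid_frequencies(g)[["beat"]]
  ph <- narrowband_phase(pp$rec$data[, e], fb, pp$rec$rate_hz)
  # 4.5 s into each trial: a whole number of beat cycles and of samples
  at_onsets <- ph[pp$rec$trial_onsets + 4.5 * pp$rec$rate_hz]
  expect_true(all(abs(wrap_phase(at_onsets - lag)) < 0.05))
})
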