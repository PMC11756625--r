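# Reference sinusoids, narrow-band phase estimation, and the complex SI.

test_that("reference sinusoids align phase zero with event onsets", {
  g <- event_grid()
  f <- grid_frequencies(g)
  rate <- 1000
  ph <- reference_sinusoid(f[["beat"]], 1.8, rate, g)
  grid_pts <- seq(0, 1500, by = 300) / 1000 * rate + 1
  expect_true(all(abs(ph[grid_pts]) < 1e-9))

  ph3 <- reference_sinusoid(f[["triple"]], 1.8, rate, g)
  expect_lt(abs(ph3[0.9 * rate + 1]), 1e-9)   # third tone, one cycle later
  half <- round(0.45 * rate) + 1               # half a 0.9 s cycle
  expect_equal(abs(ph3[half]), pi, tolerance = 1e-6)

  expect_error(reference_sinusoid(2.5, 1.8, rate, g), "commensurate")
  expect_silent(reference_sinusoid(2.5, 1.8, rate, g,
                                   check_commensurate = FALSE))
})

test_that("narrow-band phase recovers offsets and separates components", {
  rate <- 128
  fb <- 10 / 3
  ft <- 10 / 9
  t <- (0:(36 * rate - 1)) / rate
  mid <- seq(8 * rate, 28 * rate)
  ref <- wrap_phase(2 * pi * fb * t)

  ph <- narrowband_phase(cos(2 * pi * fb * t), fb, rate)
  expect_lt(max(abs(wrap_phase(ph - ref)[mid])), 0.02)

  ph2 <- narrowband_phase(cos(2 * pi * fb * t + 0.7), fb, rate)
  d <- wrap_phase(ph2 - ref)[mid]
  expect_equal(atan2(mean(sin(d)), mean(cos(d))), 0.7, tolerance = 0.01)

  mix <- cos(2 * pi * fb * t + 0.3) + cos(2 * pi * ft * t + 1.1)
  phm <- narrowband_phase(mix, fb, rate)
  phs <- narrowband_phase(cos(2 * pi * fb * t + 0.3), fb, rate)
  expect_lt(max(abs(wrap_phase(phm - phs)[mid])), 0.05)

  expect_error(narrowband_phase(rnorm(1000), 0.1, rate, bw_hz = 0.2),
               "bandwidth")
})

test_that("edge trimming removes exactly the requested samples", {
  ph <- matrix(rnorm(36 * 512 * 2), ncol = 2)
  tr <- trim_edges(ph, 512, 2)
  expect_equal(nrow(tr), 16384)               # (36 - 4) * 512
  expect_identical(trim_edges(ph, 512, 0), ph)
  expect_error(trim_edges(rnorm(300), 100, 2), "too short")
})

test_that("SI matches its closed-form values", {
  set.seed(10)
  ph <- runif(5000, -pi, pi)
  si <- synchronization_index(cbind(ph), ph)
  expect_identical(unname(c(unclass(si))), 1 + 0i)

  si2 <- synchronization_index(cbind(wrap_phase(ph + pi / 2)), ph)
  expect_equal(unname(c(unclass(si2))),
               complex(modulus = 1, argument = pi / 2), tolerance = 1e-12)

  expect_error(synchronization_index(cbind(ph), ph[-1]), "mismatched")
  expect_error(synchronization_index(list(cbind(ph), cbind(ph)),
                                     list(ph, ph, ph)), "mismatched")
})

test_that("SI null levels match theory for both variants", {
  set.seed(11)
  a <- runif(2e5, -pi, pi)
  b <- runif(2e5, -pi, pi)
  expect_equal(as.numeric(Mod(synchronization_index(cbind(a), b))), 2 / pi,
               tolerance = 0.02)
  expect_lt(Mod(synchronization_index(cbind(a), b, variant = "signed")),
            0.02)
  # signed-variant null magnitude scales as sqrt(pi / (4 N))
  set.seed(12)
  N <- 100
  mags <- replicate(400, Mod(synchronization_index(
    cbind(runif(N, -pi, pi)), runif(N, -pi, pi), variant = "signed")))
  expect_lt(abs(mean(mags) - sqrt(pi / (4 * N))), 0.02)
})

test_that("SI is linear over trials and offset-invariant", {
  set.seed(13)
  trials <- lapply(1:5, function(i) matrix(runif(600, -pi, pi), 200, 3))
  refs <- lapply(1:5, function(i) runif(200, -pi, pi))
  pooled <- synchronization_index(trials, refs)
  per_trial <- sapply(1:5, function(i)
    synchronization_index(trials[[i]], refs[[i]]))
  expect_equal(unname(c(unclass(pooled))), unname(rowMeans(per_trial)),
               tolerance = 1e-12)

  shifted <- synchronization_index(
    lapply(trials, function(m) wrap_phase(m + 1.3)),
    lapply(refs, function(r) wrap_phase(r + 1.3)))
  expect_equal(c(unclass(pooled)), c(unclass(shifted)), tolerance = 1e-9)

  # |SI| <= 1 over random cases
  for (k in 1:20) {
    si <- synchronization_index(matrix(runif(400, -pi, pi), 100, 4),
                                runif(100, -pi, pi))
    expect_true(all(Mod(si) <= 1 + 1e-12))
  }
})

test_that("si_map recovers a noiseless injected component", {
  g <- event_grid()
  cfg <- generative_config(beat = c(base = 5, slope = 0, onset = 20),
                           duple = c(base = 0, slope = 0, onset = 33),
                           triple = c(base = 0, slope = 0, onset = 33),
                           pink_sd = 0, white_sd = 0.01, n_trials = 2,
                           lag_jitter_sd = 0)
  meta <- list(subject_id = "Z1", ga_record_weeks = 34, seed = 31)
  rec <- simulate_subject(meta, g, cfg, make_montage(64))
  pp <- preprocess(rec, target_hz = 128)
  sm <- si_map(pp$rec, g, grid_frequencies(g), keep = pp$keep)
  w <- frontocentral_profile(pp$rec$montage)
  expect_gt(min(Mod(sm$si[w > 0.5, 1])), 0.99)
  # preferred phase ~ 0 on profile electrodes (signed variant)
  sg <- si_map(pp$rec, g, grid_frequencies(g)[1], variant = "signed",
               keep = pp$keep)
  expect_lt(max(abs(Arg(sg$si[w > 0.5, 1]))), 0.1)
  expect_error(si_map(pp$rec, g, 10 / 3, keep = integer(0)), "no trials")
})
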