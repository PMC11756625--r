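# Group-level statistics against hand computations and brute-force oracles.

test_that("z-scoring standardizes across subjects", {
  expect_equal(zscore_population(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore_population(c(1, 2, 3), population = TRUE),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(30)
  z <- zscore_population(matrix(rnorm(40), 10, 4))
  expect_lt(max(abs(colSums(z))), 1e-10)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_error(zscore_population(rep(2, 5)), "zero variance")
  expect_error(zscore_population(c(1, 2)), "at least 3")
})

test_that("Spearman correlation matches the midrank oracle", {
  expect_equal(spearman_corr(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_corr(1:6, -(1:6))$rho, -1)

  x <- 1:5
  y <- c(3, 1, 4, 1, 5)
  r <- spearman_corr(x, y)
  expect_equal(r$rho, spearman_brute(x, y), tolerance = 1e-10)
  tstat <- r$rho * sqrt((5 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tstat), 3), tolerance = 1e-10)

  set.seed(31)
  for (k in 1:50) {
    n <- sample(5:30, 1)
    a <- sample(1:8, n, replace = TRUE)   # plenty of ties
    b <- rnorm(n)
    expect_equal(spearman_corr(a, b)$rho, spearman_brute(a, b),
                 tolerance = 1e-10)
  }
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("Lilliefors test is calibrated and matches nortest's statistic", {
  set.seed(32)
  x <- rnorm(80)
  ours <- lilliefors_test(x, n_sim = 2000)
  ref <- nortest::lillie.test(x)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 0.12)

  hits_norm <- hits_unif <- 0
  for (k in 1:50) {
    set.seed(400 + k)
    if (lilliefors_test(rnorm(500), n_sim = 2000)$p > 0.05) {
      hits_norm <- hits_norm + 1
    }
    if (lilliefors_test(runif(500), n_sim = 2000)$p < 0.01) {
      hits_unif <- hits_unif + 1
    }
  }
  expect_gte(hits_norm, 45)
  expect_gte(hits_unif, 45)
})

test_that("Pearson correlation handles exact linearity", {
  x <- rnorm(20)
  expect_equal(pearson_corr(x, 2 * x)$r, 1, tolerance = 1e-12)
  expect_error(pearson_corr(rep(1, 6), rnorm(6)), "degenerate")
})

test_that("Rayleigh test matches resultant-length arithmetic", {
  r <- rayleigh_test(rep(1.2, 10))
  expect_equal(r$R, 1, tolerance = 1e-12)
  expect_equal(r$z, 10, tolerance = 1e-12)

  even <- seq(0, 2 * pi, length.out = 9)[1:8]
  r2 <- rayleigh_test(even)
  expect_lt(r2$z, 1e-20)
  expect_equal(r2$p, 1, tolerance = 1e-6)

  set.seed(33)
  for (k in 1:20) {
    a <- runif(sample(5:40, 1), -pi, pi)
    expect_equal(rayleigh_test(a)$z, rayleigh_brute(a), tolerance = 1e-10)
  }

  # power: von Mises kappa = 2, n = 23 rejects essentially always
  hits <- 0
  for (k in 1:50) {
    set.seed(500 + k)
    if (rayleigh_test(rvonmises(23, 0.4, 2))$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("circular-linear correlation matches its formula and detects structure", {
  set.seed(34)
  x <- seq(-1, 1, length.out = 40)
  theta <- 0.8 * x + rnorm(40, 0, 0.02)     # linear within (-pi, pi)
  r <- circ_linear_corr(theta, x)
  expect_gt(r$Rc, 0.99)
  expect_lt(r$p, 1e-6)

  for (k in 1:20) {
    a <- runif(sample(8:40, 1), -pi, pi)
    v <- rnorm(length(a))
    ours <- circ_linear_corr(a, v)
    expect_equal(ours$Rc, circlin_brute(a, v), tolerance = 1e-10)
    expect_equal(ours$p, pchisq(length(a) * ours$Rc^2, 2,
                                lower.tail = FALSE), tolerance = 1e-12)
  }

  ps <- sapply(1:100, function(k) {
    set.seed(600 + k)
    circ_linear_corr(runif(30, -pi, pi), rnorm(30))$p
  })
  expect_gt(mean(ps), 0.3)   # roughly uniform under the null
  expect_lt(mean(ps), 0.7)

  expect_error(circ_linear_corr(rep(0.3, 10), rnorm(10)), "constant|degenerate")
})

test_that("mixed ANOVA reproduces the design degrees of freedom", {
  set.seed(35)
  make_df <- function(offset = 0) {
    subj <- sprintf("S%02d", 1:46)
    grp <- rep(c("younger", "older"), each = 23)
    do.call(rbind, lapply(c("beat", "duple", "triple"), function(f) {
      data.frame(subject = subj, group = grp, frequency = f,
                 value = rnorm(46) + ifelse(grp == "older", offset, 0))
    }))
  }
  res <- mixed_anova(make_df())
  expect_equal(res["group", "df1"], 1)
  expect_equal(res["group", "df2"], 44)
  expect_equal(res["frequency", "df1"], 2)
  expect_equal(res["frequency", "df2"], 88)
  expect_equal(res["group:frequency", "df2"], 88)

  # group offset drives F and partial eta^2 monotonically
  f1 <- mixed_anova(make_df(1))["group", "F"]
  f3 <- mixed_anova(make_df(3))["group", "F"]
  expect_gt(f3, f1)
  expect_gt(mixed_anova(make_df(3))["group", "peta2"], 0.5)

  bad <- make_df()[-1, ]
  expect_error(mixed_anova(bad), "missing cells")
})

test_that("t-test modes behave at their boundary cases", {
  r <- si_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  x <- c(0.2, 0.3, 0.4, 0.5)
  r2 <- si_ttest(x, mode = "one_sample_one_tailed", threshold = mean(x))
  expect_equal(r2$p, 0.5, tolerance = 1e-12)

  set.seed(36)
  a <- rnorm(23)
  b <- rnorm(23) + 2
  expect_lt(si_ttest(b, a)$p, 0.001)
  expect_error(si_ttest(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("AIC Bayes factors follow the stated convention", {
  expect_equal(bayes_factor_aic(10, 10)$bf_effect_over_null, 1)
  r <- bayes_factor_aic(10, 12)   # null favored by 2 AIC units
  expect_equal(r$bf_null_over_effect, exp(1), tolerance = 1e-12)
  expect_equal(r$bf_effect_over_null, exp(-1), tolerance = 1e-12)
  # exp(-1) = 0.368 sits just above the 0.33 null-support bound
  expect_false(r$supports_null)
  expect_true(bayes_factor_aic(10, 12.5)$supports_null)

  set.seed(37)
  x <- rnorm(30)
  y <- rnorm(30)
  bf <- bayes_factor_aic(lm(y ~ 1), lm(y ~ x))
  expect_true(is.finite(bf$bf_effect_over_null))
  expect_error(bayes_factor_aic(lm(y ~ 1), lm(y[-1] ~ x[-1])),
               "identical data")
})

test_that("band power isolates in-band sinusoids", {
  rate <- 128
  n <- 512
  t <- (0:(n - 1)) / rate
  A <- 3
  f0 <- 8 * rate / n           # exact bin
  arr <- array(0, c(n, 2, 3))
  for (i in 1:3) {
    arr[, 1, i] <- A * sin(2 * pi * f0 * t)
    arr[, 2, i] <- A * sin(2 * pi * 20 * t)
  }
  bp <- band_power(arr, f0 - 0.05, f0 + 0.05, rate_hz = rate)
  expect_equal(bp[1], A^2 / 2, tolerance = 1e-9)
  expect_lt(bp[2], 1e-9)
  expect_error(band_power(arr, 3.001, 3.002, rate_hz = rate), "empty band")

  # 1/f noise: band power decreases when the band is shifted upward
  set.seed(38)
  g <- event_grid()
  rec <- simulate_subject(list(subject_id = "B", ga_record_weeks = 29,
                               seed = 77), g, null_gen(n_trials = 2),
                          make_montage(64))
  ep <- epoch_recording(rec)
  lo <- band_power(ep, 1, 2)
  hi <- band_power(ep, 6, 7)
  expect_true(mean(lo) > mean(hi))
})
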