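# Surrogate nulls, erfc p-values, FDR correction, cluster detection.

test_that("surrogates are seed-reproducible and binning is faithful", {
  set.seed(20)
  E <- 4; N <- 1500; I <- 3
  eeg <- lapply(1:I, function(i) matrix(runif(N * E, -pi, pi), N, E))
  ref <- lapply(1:I, function(i) wrap_phase(2 * pi * 3.33 * (0:(N - 1)) / 128))

  s1 <- surrogate_si(eeg, ref, n = 200, seed = 5)
  s2 <- surrogate_si(eeg, ref, n = 200, seed = 5)
  expect_identical(c(unclass(s1)), c(unclass(s2)))
  expect_true(all(s1 >= 0 & s1 <= 1))

  # binned fast path vs direct computation on identical offsets
  B <- 512; h <- 2 * pi / B
  offs <- matrix(-pi + (sample(B, 50 * I, TRUE) - 0.5) * h, 50, I)
  dir <- suppressWarnings(
    surrogate_si(eeg, ref, n = 50, seed = 1, bins = NULL, offsets = offs))
  bin <- suppressWarnings(
    surrogate_si(eeg, ref, n = 50, seed = 1, bins = 512, offsets = offs))
  expect_lt(max(abs(dir - bin)), 2e-3)

  expect_warning(surrogate_si(eeg, ref, n = 50, seed = 1), "fewer than 100")
})

test_that("locked data beat every surrogate; independent data do not", {
  # time-shift surrogates derive their null from inter-trial mixing, so
  # multi-trial inputs are the relevant regime (as in the pipeline)
  set.seed(21)
  N <- 1500
  I <- 8
  refs <- lapply(1:I, function(i) wrap_phase(2 * pi * 3.33 * (0:(N - 1)) / 128))
  locked <- lapply(refs, function(r) cbind(wrap_phase(r + rnorm(N, 0, 0.1))))
  obs <- Mod(synchronization_index(locked, refs))
  surr <- surrogate_si(locked, refs, n = 1000, seed = 2)
  expect_true(all(obs > surr))

  # under independence the empirical p is > 0.05 in >= 90% of repeats
  hits <- 0
  for (k in 1:50) {
    set.seed(100 + k)
    ind <- lapply(1:I, function(i) cbind(runif(N, -pi, pi)))
    o <- Mod(synchronization_index(ind, refs))
    s <- surrogate_si(ind, refs, n = 200, seed = k)
    p_emp <- (1 + sum(s >= o)) / 201
    if (p_emp > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("surrogate permutation scheme destroys alignment too", {
  set.seed(22)
  N <- 800
  ref <- wrap_phase(2 * pi * 2 * (0:(N - 1)) / 64)
  locked <- cbind(wrap_phase(ref + rnorm(N, 0, 0.2)))
  obs <- Mod(synchronization_index(locked, ref))
  s <- suppressWarnings(surrogate_si(locked, ref, n = 60, seed = 3,
                                     scheme = "permute"))
  expect_true(all(obs > s))
  s2 <- suppressWarnings(surrogate_si(locked, ref, n = 60, seed = 3,
                                      scheme = "permute"))
  expect_identical(c(unclass(s)), c(unclass(s2)))
})

test_that("erfc p-values match Gaussian tail arithmetic", {
  null <- matrix(rnorm(3000, 0.64, 0.02), 3, 1000)
  m <- rowMeans(null)
  s <- apply(null, 1, sd)
  r <- erfc_pvalue(m, null)
  expect_equal(r$p, rep(0.5, 3), tolerance = 1e-12)
  r2 <- erfc_pvalue(m + 1.6449 * s, null)
  expect_equal(r2$p, rep(0.05, 3), tolerance = 1e-3)
  r3 <- erfc_pvalue(m - 10 * s, null)
  expect_true(all(r3$p > 0.999999))
  expect_error(erfc_pvalue(0.5, matrix(0.6, 1, 100)), "zero surrogate")
})

test_that("BH correction matches the brute-force step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(r$p_adjusted, rep(0.04, 4))
  expect_true(all(r$significant))
  expect_false(any(bh_fdr(rep(1, 10))$significant))
  expect_equal(bh_fdr(0.001)$p_adjusted, 0.001)

  set.seed(23)
  for (k in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_lt(max(abs(bh_fdr(p)$p_adjusted - bh_brute(p))), 1e-12)
  }
})

test_that("cluster detection applies the neighbor rule and components", {
  m <- make_montage(64)
  expect_length(detect_clusters(rep(FALSE, 64), m)$clusters, 0)

  one <- rep(FALSE, 64)
  one[10] <- TRUE
  expect_length(detect_clusters(one, m)$clusters, 0)

  # a clique of five mutually adjacent electrodes forms one cluster of 5
  adj <- matrix(FALSE, 8, 8)
  adj[1:5, 1:5] <- TRUE
  diag(adj) <- FALSE
  toy <- toy_montage(adj)
  mask <- c(rep(TRUE, 5), rep(FALSE, 3))
  cs <- detect_clusters(mask, toy, min_neighbors = 3)
  expect_length(cs$clusters, 1)
  expect_equal(cs$clusters[[1]], 1:5)

  expect_error(detect_clusters(rep(TRUE, 10), m), "does not match")
})

test_that("cluster detection agrees with igraph components on random masks", {
  m <- make_montage(64)
  set.seed(24)
  for (k in 1:100) {
    mask <- runif(64) < 0.35
    ours <- detect_clusters(mask, m, 3)$clusters
    oracle <- clusters_igraph(mask, m, 3)
    ours <- ours[order(vapply(ours, min, 1L))]
    expect_identical(lapply(ours, as.integer), lapply(oracle, as.integer))
  }
})
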