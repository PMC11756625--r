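# Shared fixtures and independent brute-force oracles used across tests.

.cache <- new.env(parent = emptyenv())

# 46-subject desk-scale pipeline run, computed once per test session.
headline_run <- function() {
  if (is.null(.cache$headline)) {
    .cache$headline <- run_pipeline(pipeline_config(seed = 1))
  }
  .cache$headline
}

# Zero-coupling (null) generative config.
null_gen <- function(...) {
  generative_config(beat = c(base = 0, slope = 0, onset = 28),
                    duple = c(base = 0, slope = 0, onset = 33),
                    triple = c(base = 0, slope = 0, onset = 33), ...)
}

# Null-cohort pipeline run shared between calibration checks.
null_run <- function() {
  if (is.null(.cache$nullrun)) {
    .cache$nullrun <- run_pipeline(
      pipeline_config(seed = 41, n_subjects = 10, gen = null_gen()))
  }
  .cache$nullrun
}

tiny_config <- function(seed) {
  pipeline_config(seed = seed, n_subjects = 6, n_surrogates = 150,
                  gen = generative_config(n_trials = 3))
}

# Small pipeline run shared by the orchestration tests.
tiny_run <- function() {
  if (is.null(.cache$tiny)) .cache$tiny <- run_pipeline(tiny_config(9))
  .cache$tiny
}

# Brute-force Benjamini-Hochberg step-up adjustment.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n > 1) for (i in seq(n - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Midranks computed from scratch (no rank()).
midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Spearman rho via explicit midranks + hand-rolled Pearson sums.
spearman_brute <- function(x, y) {
  rx <- midrank(x)
  ry <- midrank(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxy / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Rayleigh statistic via the complex resultant.
rayleigh_brute <- function(a) {
  R <- Mod(mean(exp(1i * a)))
  length(a) * R^2
}

# Circular-linear correlation from raw sums (no cor()).
circlin_brute <- function(a, x) {
  pear <- function(u, v) {
    n <- length(u)
    (sum(u * v) - sum(u) * sum(v) / n) /
      sqrt((sum(u^2) - sum(u)^2 / n) * (sum(v^2) - sum(v)^2 / n))
  }
  rcx <- pear(x, cos(a))
  rsx <- pear(x, sin(a))
  rcs <- pear(sin(a), cos(a))
  sqrt((rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2))
}

# von Mises sampler (Best & Fisher rejection method).
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1
      out[i] <- wrap_phase(mu + sign(u[3] - 0.5) * acos(f))
    }
  }
  out
}

# Tiny hand-built montage for cluster-rule unit tests.
toy_montage <- function(adj, outer = rep(FALSE, nrow(adj))) {
  n <- nrow(adj)
  structure(list(labels = sprintf("T%02d", seq_len(n)),
                 pos = diag(3)[rep(1, n), , drop = FALSE],
                 adjacency = adj, outer_ring = outer, neighbor_thr = 1),
            class = "eeg_montage")
}

# Cluster detection oracle via igraph connected components.
clusters_igraph <- function(mask, montage, min_neighbors = 3) {
  A <- montage$adjacency
  keep <- mask & as.vector(A %*% mask) >= min_neighbors
  idx <- which(keep)
  if (!length(idx)) return(list())
  g <- igraph::graph_from_adjacency_matrix(A[idx, idx, drop = FALSE],
                                           mode = "undirected")
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(k) sort(idx[comp$membership == k]))
  out <- out[vapply(out, length, 1L) > min_neighbors]
  out[order(vapply(out, min, 1L))]
}
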