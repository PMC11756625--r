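# Population-level statistics: z-scored coupling strength vs gestational
# age, circular phase statistics, the 3x2 mixed ANOVA, t-tests, AIC-based
# Bayes factors, and spectral band-power controls.

#' z-score values across subjects
#'
#' Population-level standardization of |SI| at each electrode: columns of a
#' subjects x electrodes matrix are centered and scaled. Sample (n-1)
#' standard deviation by default; `population = TRUE` uses n.
#'
#' @param x numeric vector (one electrode) or matrix (subjects x
#'   electrodes).
#' @param population use the population (n) denominator.
#' @return z-scores, same shape as `x`.
#' @export
zscore_population <- function(x, population = FALSE) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(xm) < 3) stop("need at least 3 subjects to z-score")
  denom <- if (population) nrow(xm) else nrow(xm) - 1
  m <- colMeans(xm)
  s <- sqrt(colSums((xm - rep(m, each = nrow(xm)))^2) / denom)
  if (any(s <= 0)) stop("zero variance: cannot z-score")
  z <- (xm - rep(m, each = nrow(xm))) / rep(s, each = nrow(xm))
  if (vec) drop(z) else z
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman correlation with a two-tailed p-value from the
#' t approximation (via [stats::cor.test()] with `exact = FALSE`).
#'
#' @param x,y numeric vectors, length >= 4.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, length >= 5.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("degenerate variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Cached Monte-Carlo null distributions of the Lilliefors statistic,
# keyed by (n, n_sim, mc_seed).
.lillie_cache <- new.env(parent = emptyenv())

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  Fz <- stats::pnorm(z)
  i <- seq_len(n)
  max(max(i / n - Fz), max(Fz - (i - 1) / n))
}

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov distance between the empirical distribution and a
#' normal with estimated mean and sd, with the p-value calibrated by Monte
#' Carlo: `n_sim` seeded draws of the statistic under normality (the null
#' table is cached per sample size). Deterministic given `mc_seed`.
#'
#' @param x numeric vector, length >= 5.
#' @param n_sim Monte-Carlo draws for the null table.
#' @param mc_seed seed for the null draws.
#' @return list with `statistic`, `p`, `n`.
#' @export
lilliefors_test <- function(x, n_sim = 10000, mc_seed = 20260101) {
  n <- length(x)
  stopifnot(n >= 5)
  if (stats::sd(x) == 0) stop("degenerate variance")
  D <- lilliefors_stat(x)
  key <- paste(n, n_sim, mc_seed, sep = "_")
  if (is.null(.lillie_cache[[key]])) {
    set.seed(mc_seed)
    .lillie_cache[[key]] <- vapply(seq_len(n_sim), function(i) {
      lilliefors_stat(rnorm(n))
    }, numeric(1))
  }
  null <- .lillie_cache[[key]]
  list(statistic = D, p = (1 + sum(null >= D)) / (n_sim + 1), n = n)
}

#' Rayleigh test of circular uniformity
#'
#' `z = n * R^2` with `R` the mean resultant length; p-value by the Zar
#' small-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` where `Rn = n * R`.
#'
#' @param angles numeric vector of angles in radians (n >= 3).
#' @return list with `z`, `p`, `R` (mean resultant length), `mean_angle`,
#'   `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  stopifnot(n >= 3)
  C <- sum(cos(angles))
  S <- sum(sin(angles))
  Rn <- sqrt(C^2 + S^2)
  R <- Rn / n
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(z = z, p = min(1, p), R = R, mean_angle = atan2(S, C), n = n)
}

#' Circular-linear correlation
#'
#' Correlation between an angular variable and a linear covariate:
#' `Rc^2 = (r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2)` with
#' `r_cx = cor(x, cos(theta))`, `r_sx = cor(x, sin(theta))`,
#' `r_cs = cor(sin(theta), cos(theta))`; p-value from `n * Rc^2` against a
#' chi-squared distribution with 2 degrees of freedom.
#'
#' @param angles angular variable (radians).
#' @param x linear covariate, same length (n >= 5).
#' @return list with `Rc`, `p`, `n`.
#' @export
circ_linear_corr <- function(angles, x) {
  n <- length(angles)
  stopifnot(n == length(x), n >= 5)
  ct <- cos(angles)
  st <- sin(angles)
  if (stats::sd(ct) == 0 && stats::sd(st) == 0) stop("constant angle series")
  if (stats::sd(x) == 0 || stats::sd(ct) == 0 || stats::sd(st) == 0) {
    stop("degenerate component variance")
  }
  rcx <- stats::cor(x, ct)
  rsx <- stats::cor(x, st)
  rcs <- stats::cor(st, ct)
  Rc2 <- (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2)
  Rc2 <- max(0, min(1, Rc2))
  list(Rc = sqrt(Rc2), p = stats::pchisq(n * Rc2, 2, lower.tail = FALSE),
       n = n)
}

#' 3 x 2 mixed ANOVA
#'
#' Classical mixed-model decomposition with frequency (3 levels) as the
#' within-subject factor and age group (2 levels) as the between-subject
#' factor, fitted via [stats::aov()] with an `Error(subject)` stratum.
#' Requires a balanced, complete design (every subject measured at every
#' frequency). Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)` within each stratum.
#'
#' @param data data.frame with columns `subject`, `group`, `frequency`,
#'   `value`.
#' @return object of class `mixed_anova`: data.frame with one row per
#'   effect (`group`, `frequency`, `group:frequency`): `F`, `df1`, `df2`,
#'   `p`, `peta2`.
#' @export
mixed_anova <- function(data) {
  stopifnot(all(c("subject", "group", "frequency", "value") %in%
                  names(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$frequency <- factor(data$frequency)
  tab <- table(data$subject, data$frequency)
  if (any(tab != 1)) stop("missing cells: each subject needs one value per frequency")
  fit <- stats::aov(value ~ group * frequency + Error(subject),
                    data = data)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- which(trimws(rownames(tab)) == term)
    e <- which(trimws(rownames(tab)) == "Residuals")
    c(F = tab[i, "F value"], df1 = tab[i, "Df"], df2 = tab[e, "Df"],
      p = tab[i, "Pr(>F)"],
      peta2 = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + tab[e, "Sum Sq"]))
  }
  out <- rbind(group = pick(between, "group"),
               frequency = pick(within, "frequency"),
               `group:frequency` = pick(within, "group:frequency"))
  out <- as.data.frame(out)
  out$effect <- rownames(out)
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-16s F(%d,%d) = %.2f, p = %.4g, partial eta^2 = %.3f\n",
                x$effect[i], x$df1[i], x$df2[i], x$F[i], x$p[i],
                x$peta2[i]))
  }
  invisible(x)
}

#' t-tests on coupling strength or band power
#'
#' `mode = "two_sample"`: Welch two-sample t-test between `x` and `y`.
#' `mode = "one_sample_one_tailed"`: upper one-tailed one-sample test of
#' whether the mean of `x` exceeds `threshold` (e.g. the surrogate 95%
#' confidence bound).
#'
#' @param x numeric vector (n >= 3).
#' @param y second sample for the two-sample mode.
#' @param mode test mode.
#' @param threshold null value for the one-sample mode.
#' @return list with `t`, `df`, `p`, `mode`.
#' @export
si_ttest <- function(x, y = NULL,
                     mode = c("two_sample", "one_sample_one_tailed"),
                     threshold = 0) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0 || (!is.null(y) && stats::sd(y) == 0)) {
    stop("zero variance")
  }
  tt <- if (mode == "two_sample") {
    stopifnot(!is.null(y), length(y) >= 3)
    stats::t.test(x, y)
  } else {
    stats::t.test(x, mu = threshold, alternative = "greater")
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mode = mode)
}

#' AIC-based Bayes factor between null and effect models
#'
#' `BF_effect/null = exp((AIC_null - AIC_effect) / 2)`: values below 0.33
#' are read as evidence supporting the null hypothesis, values above 3 as
#' evidence for the effect. The reciprocal orientation is returned as well
#' and both are labelled explicitly to avoid confusion.
#'
#' @param fit_null,fit_effect fitted models (anything with [stats::AIC()]
#'   and [stats::nobs()] methods), fitted to the same data, or bare AIC
#'   values (`numeric(1)`).
#' @return list with `bf_effect_over_null`, `bf_null_over_effect`,
#'   `aic_null`, `aic_effect`, `supports_null` (BF_effect/null <= 0.33).
#' @export
bayes_factor_aic <- function(fit_null, fit_effect) {
  aicv <- function(f) if (is.numeric(f) && length(f) == 1) f else
    stats::AIC(f)
  if (!is.numeric(fit_null) && !is.numeric(fit_effect)) {
    if (stats::nobs(fit_null) != stats::nobs(fit_effect)) {
      stop("models were not fit to identical data")
    }
  }
  a0 <- aicv(fit_null)
  a1 <- aicv(fit_effect)
  if (!is.finite(a0) || !is.finite(a1)) stop("non-finite AIC")
  bf10 <- exp((a0 - a1) / 2)
  list(bf_effect_over_null = bf10, bf_null_over_effect = 1 / bf10,
       aic_null = a0, aic_effect = a1, supports_null = bf10 <= 0.33)
}

#' Average spectral power in a frequency band
#'
#' Per-trial DFT power (one-sided; a sinusoid of amplitude A in-band
#' contributes A^2/2 at its bin), averaged across trials and then across
#' frequency bins within `[f_lo, f_hi]`, per electrode.
#'
#' @param epochs an `eeg_epochs` object (or a samples x electrodes x trials
#'   array with a `rate_hz` argument).
#' @param f_lo,f_hi band edges in Hz.
#' @param rate_hz required when `epochs` is a bare array.
#' @return numeric vector: average band power per electrode.
#' @export
band_power <- function(epochs, f_lo, f_hi, rate_hz = NULL) {
  if (inherits(epochs, "eeg_epochs")) {
    arr <- epochs$trials
    rate_hz <- epochs$rate_hz
  } else {
    arr <- epochs
    stopifnot(!is.null(rate_hz))
  }
  stopifnot(f_lo < f_hi, f_hi < rate_hz / 2)
  n <- dim(arr)[1]
  freqs <- (seq_len(floor(n / 2) + 1) - 1) * rate_hz / n
  sel <- which(freqs >= f_lo & freqs <= f_hi)
  if (!length(sel)) stop("empty band: no DFT bins in [f_lo, f_hi]")
  ntr <- dim(arr)[3]
  pow <- 0
  for (i in seq_len(ntr)) {
    X <- stats::mvfft(arr[, , i])
    P <- 2 * Mod(X[sel, , drop = FALSE])^2 / n^2
    pow <- pow + P
  }
  colMeans(pow / ntr)
}
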