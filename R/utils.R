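# Shared numeric helpers. All filtering in this package is zero-phase and is
# carried out in the frequency domain; see fir_filtfilt_fft() below.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector/matrix of angles in radians.
#' @return angles wrapped to the interval (-pi, pi].
#' @examples
#' wrap_phase(3 * pi / 2)  # -pi/2
#' @export
wrap_phase <- function(x) {
  y <- atan2(sin(x), cos(x))
  # atan2 maps pi to pi and -pi to pi only up to sign of the zero; force -pi -> pi
  y[y <= -pi] <- pi
  y
}

#' Analytic signal via the Hilbert transform
#'
#' Computes the analytic signal z = x + i*H(x) using the FFT one-sided
#' spectrum construction. Columns of a matrix are treated as channels.
#'
#' @param x numeric vector or matrix (samples in rows).
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  X <- stats::mvfft(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::mvfft(X * h, inverse = TRUE) / n
  if (vec) drop(z) else z
}

# Next fast FFT length (products of 2, 3, 5).
next_fast_len <- function(n) {
  stats::nextn(n, factors = c(2, 3, 5))
}

# Zero-phase (two-pass) FIR filtering via the frequency domain.
#
# Multiplying the spectrum by |H(w)|^2 is exactly equivalent to applying the
# FIR filter h forward and backward (convolution with the autocorrelation of
# h, which is symmetric about zero lag, hence zero net phase). Edges are
# handled by reflection padding of length(h) samples on each side, and enough
# zero padding is added to avoid circular wrap-around in the retained region.
#
# x: vector or matrix (samples in rows); h: FIR coefficients.
# analytic: if TRUE, additionally return the analytic (complex) signal of the
# filtered data, computed on the padded segment.
fir_filtfilt_fft <- function(x, h, analytic = FALSE) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  L <- length(h)
  pad <- min(L, n - 1L)
  top <- xm[seq(pad + 1L, 2L), , drop = FALSE]
  bot <- xm[seq(n - 1L, n - pad), , drop = FALSE]
  xp <- rbind(top, xm, bot)
  np <- nrow(xp)
  N <- next_fast_len(np + L)
  xp <- rbind(xp, matrix(0, N - np, ncol(xm)))
  H2 <- Mod(stats::fft(c(h, numeric(N - L))))^2
  X <- stats::mvfft(xp)
  if (analytic) {
    mask <- numeric(N)
    if (N %% 2 == 0) {
      mask[c(1, N / 2 + 1)] <- 1
      mask[2:(N / 2)] <- 2
    } else {
      mask[1] <- 1
      mask[2:((N + 1) / 2)] <- 2
    }
    Y <- stats::mvfft(X * (H2 * mask), inverse = TRUE) / N
    out <- Y[seq(pad + 1L, pad + n), , drop = FALSE]
  } else {
    Y <- stats::mvfft(X * H2, inverse = TRUE) / N
    out <- Re(Y[seq(pad + 1L, pad + n), , drop = FALSE])
  }
  if (vec) drop(out) else out
}

# Design the package's standard FIR filters (Hamming-windowed, signal::fir1).
# Band-pass: order = 3 cycles of the low cutoff (EEGLAB convention).
design_bandpass <- function(low_hz, high_hz, rate_hz) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < rate_hz / 2)
  ord <- ceiling(3 * rate_hz / low_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(low_hz, high_hz) / (rate_hz / 2), type = "pass")
}

# Narrow-band: order = 3 * rate / bandwidth (one-sided transition ~ bandwidth).
design_narrowband <- function(center_hz, bw_hz, rate_hz) {
  stopifnot(bw_hz > 0, center_hz - bw_hz / 2 > 0,
            center_hz + bw_hz / 2 < rate_hz / 2)
  ord <- ceiling(3 * rate_hz / bw_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  signal::fir1(ord, c(center_hz - bw_hz / 2, center_hz + bw_hz / 2) /
                 (rate_hz / 2), type = "pass")
}

# FFT (trigonometric) resampling of columns to m samples. Exact for signals
# band-limited below the target Nyquist frequency. The target bin count must
# be smaller than the source (downsampling only).
fft_resample <- function(x, m) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  stopifnot(m < n, m >= 2)
  X <- stats::mvfft(xm)
  keep <- floor(m / 2)
  Y <- matrix(0 + 0i, m, ncol(xm))
  Y[1, ] <- X[1, ]
  if (keep >= 2) {
    Y[2:keep, ] <- X[2:keep, , drop = FALSE]
    Y[seq(m, m - keep + 2), ] <- X[seq(n, n - keep + 2), , drop = FALSE]
  }
  # new Nyquist bin left at zero: inputs are low-passed well below it
  out <- Re(stats::mvfft(Y, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

# Deterministic derivation of per-subject / per-stage seeds from a master
# seed. Kept below 2^31 - 1. Lehmer-style mix.
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  ((48271 * s + 7919 * (as.numeric(k) + 1)) %% (m - 1)) + 1
}

# Row-wise standard deviations (sample, n-1).
row_sds <- function(x) {
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
}

# Complementary error function.
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
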