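# Surrogate-based inference on coupling strength: surrogate SI
# distributions from shuffled reference sinusoids, Gaussian (erfc) p-values,
# Benjamini-Hochberg correction across electrodes, and sensor-space cluster
# detection under the montage adjacency.

#' Surrogate SI null distribution
#'
#' Recomputes the SI between the intact EEG phases and a shuffled reference,
#' `n` times. The default scheme, `"timeshift"`, shifts the underlying
#' reference sinusoid in time by an independent uniform random amount per
#' trial; for a pure sinusoid this equals adding a uniform random constant
#' to its phase series, which preserves the marginal phase distribution
#' while destroying the stimulus alignment. `"permute"` randomly permutes
#' the reference samples within each trial instead.
#'
#' For the `"absolute"` variant with `bins` set (default 512), the surrogate
#' magnitudes are computed from a binned representation of the per-trial
#' phase-difference distribution (offsets quantized to the bin grid); this
#' is numerically indistinguishable from the direct computation (~1e-3,
#' dominated by bin width ~0.012 rad) and orders of magnitude faster.
#' `bins = NULL` forces the direct computation. The signed variant has an
#' exact closed form under time shifting and never bins.
#'
#' @param eeg_phases matrix (samples x electrodes) or list of such matrices
#'   (one per trial).
#' @param ref_phases reference phase vector or per-trial list.
#' @param n number of surrogates (values below 100 trigger a warning:
#'   unstable tail estimates).
#' @param scheme `"timeshift"` (default) or `"permute"`.
#' @param seed RNG seed; identical seeds give identical surrogates.
#' @param variant `"absolute"` or `"signed"` (see
#'   [synchronization_index()]).
#' @param bins number of phase bins for the fast path, or `NULL` for direct
#'   computation.
#' @param offsets optional n x n_trials matrix of phase offsets (radians),
#'   overriding the RNG (for reproducibility studies).
#' @return object of class `surrogate_null`: numeric matrix (electrodes x
#'   n) of surrogate |SI| values, with attributes `scheme`, `seed`,
#'   `variant`.
#' @export
surrogate_si <- function(eeg_phases, ref_phases, n = 1000,
                         scheme = c("timeshift", "permute"), seed = 1,
                         variant = c("absolute", "signed"), bins = 512,
                         offsets = NULL) {
  scheme <- match.arg(scheme)
  variant <- match.arg(variant)
  if (n < 100) warning("fewer than 100 surrogates: tail estimates unstable")
  dlist <- phase_diff_list(eeg_phases, ref_phases)
  if (scheme == "permute") {
    if (!is.list(eeg_phases)) eeg_phases <- list(eeg_phases)
    if (!is.list(ref_phases)) ref_phases <- list(ref_phases)
    if (length(ref_phases) == 1) {
      ref_phases <- rep(ref_phases, length(eeg_phases))
    }
    set.seed(seed)
    out <- vapply(seq_len(n), function(k) {
      dk <- mapply(function(e, r) {
        wrap_phase(as.matrix(e) - r[sample.int(length(r))])
      }, eeg_phases, ref_phases, SIMPLIFY = FALSE)
      Mod(si_from_diffs(dk, variant))
    }, numeric(ncol(dlist[[1]])))
    out <- matrix(out, ncol = n)
  } else {
    out <- surrogate_timeshift(dlist, n, seed, variant, bins, offsets)
  }
  structure(out, scheme = scheme, seed = seed, variant = variant,
            class = "surrogate_null")
}

# Time-shift surrogates from phase-difference matrices. A per-trial time
# shift of the reference sinusoid subtracts a constant delta from the
# wrapped phase differences of that trial.
surrogate_timeshift <- function(dlist, n, seed, variant, bins,
                                offsets = NULL) {
  I <- length(dlist)
  E <- ncol(dlist[[1]])
  set.seed(seed)
  use_bins <- variant == "absolute" && !is.null(bins)
  if (is.null(offsets)) {
    offsets <- matrix(runif(n * I, -pi, pi), n, I)
  } else {
    stopifnot(nrow(offsets) == n, ncol(offsets) == I)
  }
  if (!use_bins) {
    # direct: loop surrogates, trig on every sample
    acc_re <- matrix(0, E, n)
    acc_im <- matrix(0, E, n)
    ntot <- 0
    for (i in seq_len(I)) {
      d <- dlist[[i]]
      ntot <- ntot + nrow(d)
      for (k in seq_len(n)) {
        dk <- d - offsets[k, i]
        acc_re[, k] <- acc_re[, k] + colSums(cos(dk))
        acc_im[, k] <- acc_im[, k] +
          if (variant == "absolute") colSums(abs(sin(dk))) else
            colSums(sin(dk))
      }
    }
    return(sqrt((acc_re / ntot)^2 + (acc_im / ntot)^2))
  }
  # binned fast path (absolute variant): per-trial histograms of d plus a
  # circulant |sin| kernel; the real part has an exact closed form.
  B <- bins
  h <- 2 * pi / B
  centers <- -pi + (seq_len(B) - 0.5) * h
  jm <- matrix(pmin(B, pmax(1, round((offsets + pi) / h + 0.5))), n, I)
  Kabs <- abs(sin(outer(centers, centers, "-")))   # B x B
  cosd <- cos(centers)
  sind <- sin(centers)
  im <- matrix(0, E, n)
  re <- matrix(0, E, n)
  for (i in seq_len(I)) {
    d <- dlist[[i]]
    N <- nrow(d)
    idx <- pmin(B, pmax(1, floor((d + pi) / h) + 1))
    off <- rep((seq_len(E) - 1) * B, each = N)
    P <- matrix(tabulate(as.vector(idx) + off, B * E), B, E) / N
    Ci <- colSums(cos(d)) / N
    Si <- colSums(sin(d)) / N
    A <- crossprod(P, Kabs)                        # E x B
    ji <- jm[, i]
    im <- im + A[, ji, drop = FALSE]
    re <- re + outer(Ci, cosd[ji]) + outer(Si, sind[ji])
  }
  sqrt((re / I)^2 + (im / I)^2)
}

#' erfc (Gaussian) p-value against a surrogate null
#'
#' Upper one-tailed p-value from the complementary-error-function method:
#' `p = 0.5 * erfc((obs - mean(null)) / (sd(null) * sqrt(2)))`, i.e. the
#' upper Gaussian tail of the surrogate distribution. The empirical rank
#' p-value is returned alongside for diagnostics.
#'
#' @param observed numeric vector of observed |SI| (one per electrode).
#' @param null `surrogate_null` matrix (electrodes x n) or a numeric vector
#'   (recycled for a single electrode).
#' @return list with `p` (erfc p-values), `p_rank` (empirical
#'   `(1 + #exceedances) / (n + 1)`), `mean`, `sd`.
#' @export
erfc_pvalue <- function(observed, null) {
  if (is.null(dim(null))) null <- matrix(null, nrow = 1)
  stopifnot(length(observed) == nrow(null), ncol(null) >= 2)
  m <- rowMeans(null)
  s <- row_sds(null)
  if (any(s <= 0)) stop("zero surrogate variance")
  z <- (observed - m) / s
  p <- 0.5 * erfc(z / sqrt(2))
  p_rank <- (1 + rowSums(null >= observed)) / (ncol(null) + 1)
  list(p = p, p_rank = p_rank, mean = m, sd = s)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the significance
#' mask at level `q`.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `p_adjusted` and logical `significant`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, significant = adj < q)
}

#' Detect sensor-space clusters of significant electrodes
#'
#' FieldTrip-style membership rule then connected components: an electrode
#' is retained when it is significant and has at least `min_neighbors`
#' significant neighbors under the montage adjacency; connected components
#' of the retained set larger than `min_neighbors` electrodes form the
#' clusters.
#'
#' @param mask logical vector, one entry per montage electrode.
#' @param montage the `eeg_montage` the mask is aligned with.
#' @param min_neighbors neighbor threshold (default 3).
#' @param p_adjusted optional adjusted p-values used to annotate each
#'   cluster with its minimum adjusted p (a reporting convention, not a
#'   cluster-mass test).
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   integer electrode indices), `labels`, `cluster_p`, `min_neighbors`.
#' @export
detect_clusters <- function(mask, montage, min_neighbors = 3,
                            p_adjusted = NULL) {
  A <- montage$adjacency
  if (length(mask) != nrow(A)) stop("mask does not match the montage")
  mask <- as.logical(mask)
  nsig <- as.vector(A %*% mask)
  keep <- mask & nsig >= min_neighbors
  comp <- integer(length(mask))
  cid <- 0
  for (v in which(keep)) {
    if (comp[v] == 0) {
      cid <- cid + 1
      queue <- v
      comp[v] <- cid
      while (length(queue)) {
        u <- queue[1]
        queue <- queue[-1]
        nb <- which(A[u, ] & keep & comp == 0)
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }
  clusters <- lapply(seq_len(cid), function(k) which(comp == k))
  clusters <- clusters[vapply(clusters, length, 1L) > min_neighbors]
  cluster_p <- if (!is.null(p_adjusted)) {
    vapply(clusters, function(cl) min(p_adjusted[cl]), numeric(1))
  } else rep(NA_real_, length(clusters))
  structure(list(clusters = clusters,
                 labels = lapply(clusters, function(cl) montage$labels[cl]),
                 cluster_p = cluster_p, min_neighbors = min_neighbors),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  if (!length(x$clusters)) {
    cat("No clusters\n")
  } else {
    for (k in seq_along(x$clusters)) {
      cat(sprintf("Cluster %d: %d electrodes%s\n", k,
                  length(x$clusters[[k]]),
                  if (is.na(x$cluster_p[k])) "" else
                    sprintf(" (min adjusted p = %.4g)", x$cluster_p[k])))
    }
  }
  invisible(x)
}
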