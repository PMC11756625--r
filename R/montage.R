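# Synthetic geodesic sensor layouts. Real HydroCel net geometries are not
# redistributable, so montages are generated as quasi-uniform Fibonacci
# lattices on a spherical cap, with an adjacency relation from an angular
# distance threshold and an outer ring flagged for exclusion.

#' Construct a synthetic geodesic montage
#'
#' Electrodes are placed quasi-uniformly on a spherical cap covering the
#' scalp (polar angle up to ~103 degrees from the vertex) using a Fibonacci
#' lattice. Two electrodes are neighbors when their angular distance is below
#' 1.55 times the median nearest-neighbor distance. The lowest 20% of
#' electrodes form the outer ring (poorest signal-to-noise in infant
#' recordings; excluded from analyses).
#'
#' Coordinates: +x anterior, +y left, +z vertex; unit sphere.
#'
#' @param n_electrodes 64 or 124.
#' @return object of class `eeg_montage`: `labels`, `pos` (n x 3 unit
#'   vectors), `adjacency` (logical n x n, symmetric, irreflexive),
#'   `outer_ring` (logical).
#' @examples
#' m <- make_montage(64)
#' sum(m$outer_ring)
#' @export
make_montage <- function(n_electrodes = 64) {
  if (!n_electrodes %in% c(64, 124)) {
    stop("unsupported electrode count; use 64 or 124")
  }
  n <- n_electrodes
  theta_max <- 1.8  # rad from vertex
  i <- seq_len(n)
  z <- 1 - (1 - cos(theta_max)) * (i - 0.5) / n
  golden <- pi * (3 - sqrt(5))
  az <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(az), y = r * sin(az), z = z)
  labels <- sprintf("E%03d", i)
  rownames(pos) <- labels
  ang <- angular_distance(pos, pos)
  diag(ang) <- Inf
  nn <- apply(ang, 1, min)
  thr <- 1.55 * stats::median(nn)
  adjacency <- ang <= thr
  diag(adjacency) <- FALSE
  n_ring <- round(0.2 * n)
  outer_ring <- rank(z, ties.method = "first") <= n_ring
  structure(list(labels = labels, pos = pos, adjacency = adjacency,
                 outer_ring = outer_ring, neighbor_thr = thr),
            class = "eeg_montage")
}

# Pairwise angular (great-circle) distance between rows of unit matrices.
angular_distance <- function(a, b) {
  d <- tcrossprod(a, b)
  acos(pmin(pmax(d, -1), 1))
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("Synthetic geodesic montage: %d electrodes (%d outer ring), median degree %g\n",
              length(x$labels), sum(x$outer_ring),
              stats::median(rowSums(x$adjacency))))
  invisible(x)
}

#' @export
plot.eeg_montage <- function(x, highlight = NULL, values = NULL, ...) {
  # azimuthal equidistant projection from the vertex
  th <- acos(pmin(pmax(x$pos[, 3], -1), 1))
  az <- atan2(x$pos[, 2], x$pos[, 1])
  px <- th * cos(az)
  py <- th * sin(az)
  col <- rep("grey40", length(px))
  if (!is.null(values)) {
    pal <- colorRampPalette(c("navy", "white", "firebrick"))(100)
    v <- (values - min(values)) / max(1e-12, diff(range(values)))
    col <- pal[pmax(1, ceiling(v * 100))]
  }
  plot(px, py, asp = 1, pch = 21, bg = col, cex = 1.6,
       xlab = "", ylab = "", axes = FALSE, ...)
  if (!is.null(highlight) && length(highlight)) {
    points(px[highlight], py[highlight], pch = 4, cex = 2, lwd = 2)
  }
  points(px[x$outer_ring], py[x$outer_ring], pch = 1, cex = 2.2, col = "grey70")
  invisible(x)
}

# Subset a montage to the given electrode indices.
montage_subset <- function(montage, idx) {
  structure(list(labels = montage$labels[idx],
                 pos = montage$pos[idx, , drop = FALSE],
                 adjacency = montage$adjacency[idx, idx, drop = FALSE],
                 outer_ring = montage$outer_ring[idx],
                 neighbor_thr = montage$neighbor_thr),
            class = "eeg_montage")
}

#' Frontocentral spatial profile
#'
#' Gaussian weighting (in angular distance) around a point tilted 30 degrees
#' anterior of the vertex, emulating the frontocentral topography of the
#' neonatal auditory response. Weights below `floor` are set to exactly zero
#' so that "off-profile" electrodes carry no signal.
#'
#' @param montage an [make_montage()] result.
#' @param tilt_rad anterior tilt of the profile center from the vertex.
#' @param sigma_rad Gaussian width in radians.
#' @param floor weights below this are zeroed.
#' @return numeric vector of weights in `[0, 1]`, one per electrode.
#' @export
frontocentral_profile <- function(montage, tilt_rad = 0.52, sigma_rad = 0.8,
                                  floor = 0.05) {
  center <- c(sin(tilt_rad), 0, cos(tilt_rad))
  ang <- angular_distance(montage$pos, matrix(center, 1))
  w <- exp(-(ang / sigma_rad)^2)
  w[w < floor] <- 0
  drop(w)
}
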