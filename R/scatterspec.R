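#' Unit-sphere point model of a nucleus arrangement
#'
#' Models the embryo as identical repeating units: every nucleus is replaced
#' by a small sphere at its centroid, removing size/shape variability so the
#' Fourier power spectrum factors into a common form function times the
#' structure function of the centroid arrangement. Centroids (in
#' micrometres) are mapped onto a cubic `grid^3` lattice with a single
#' isotropic scale chosen so the physical extent of the source volume fits
#' the grid (aspect preserved), and a radius-1-voxel digital ball (the
#' centre voxel plus its 6 face neighbours) is stamped at each mapped
#' centroid. Overlapping stamps merge (union semantics) and are counted in
#' attribute `n_overlap`.
#'
#' @param centroids_um numeric matrix (n x 3) of nucleus centroids in
#'   micrometres.
#' @param extent_um physical edge lengths (length 3) of the source volume in
#'   micrometres; defaults to the span of the centroids plus a 2 um margin.
#' @param grid lattice size per axis (256 matches a 256-point FFT).
#' @param radius_vox stamp radius in voxels (1 = the 7-voxel digital ball).
#' @return a `point_model` object: 0/1 array with attributes
#'   `voxel_um` (grid spacing), `n_points`, `n_overlap`.
#' @export
build_point_model <- function(centroids_um, extent_um = NULL, grid = 256L,
                              radius_vox = 1L) {
  centroids_um <- as.matrix(centroids_um)
  stopifnot(ncol(centroids_um) == 3L, nrow(centroids_um) >= 1L)
  if (is.null(extent_um)) {
    extent_um <- apply(centroids_um, 2, function(v) diff(range(v))) + 4
  }
  extent_um <- rep_len(extent_um, 3L)
  span <- apply(centroids_um, 2, function(v) diff(range(v)))
  if (any(span > extent_um + 1e-9)) stop("centroid out of bounds")
  voxel_um <- max(extent_um) / grid
  # centre the cloud on the grid
  mid <- (apply(centroids_um, 2, min) + apply(centroids_um, 2, max)) / 2
  ijk <- round(sweep(centroids_um, 2, mid) / voxel_um) + (grid %/% 2L) + 1L
  if (any(ijk < 1L + radius_vox) || any(ijk > grid - radius_vox)) {
    stop("centroid out of bounds: source volume larger than stated extent")
  }
  arr <- array(0, c(grid, grid, grid))
  off <- expand.grid(dx = -radius_vox:radius_vox, dy = -radius_vox:radius_vox,
    dz = -radius_vox:radius_vox)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius_vox^2, ]
  n_overlap <- 0L
  for (i in seq_len(nrow(ijk))) {
    vox <- cbind(ijk[i, 1] + off$dx, ijk[i, 2] + off$dy, ijk[i, 3] + off$dz)
    prev <- arr[vox]
    if (any(prev > 0)) n_overlap <- n_overlap + 1L
    arr[vox] <- 1
  }
  structure(arr,
    voxel_um = voxel_um, n_points = nrow(ijk), n_overlap = n_overlap,
    radius_vox = radius_vox, class = "point_model"
  )
}

#' Radially averaged scattering power spectrum
#'
#' Computes the 3D discrete Fourier transform of the point model
#' (unnormalized forward transform), takes the squared modulus as the
#' power, and shell-averages it over 256 radial spatial-frequency levels.
#' Frequencies are physical: `k = 2 * pi * u / voxel_um` rad/um along each
#' axis. The first bin holds the DC (`k = 0`) value alone; the remaining
#' bins partition `(0, k_max]` evenly, each collecting the mean power over
#' the thin spherical shell between successive levels.
#'
#' @param model a [build_point_model()] result.
#' @param n_bins number of radial levels (default 256).
#' @return a `scattering_spectrum` object: list with `k` (bin-centre
#'   spatial frequencies, rad/um; first entry 0), `power` (mean power per
#'   shell), `peak_power`.
#' @export
compute_spectrum <- function(model, n_bins = 256L) {
  arr <- unclass(model)
  if (all(arr == 0)) stop("all-zero point model")
  voxel_um <- attr(model, "voxel_um")
  d <- dim(arr)
  P <- Mod(fft(arr))^2
  freq_axis <- function(n) {
    half <- floor(n / 2)
    2 * pi * c(0:(n - half - 1), -half:-1) / (n * voxel_um)
  }
  kx <- freq_axis(d[1])
  ky <- freq_axis(d[2])
  kz <- freq_axis(d[3])
  k2 <- outer(outer(kx^2, ky^2, "+"), kz^2, "+")
  kmag <- sqrt(k2)
  kmax <- max(kmag)
  # bin 1: DC alone; bins 2..n_bins: uniform shells over (0, kmax]
  edges <- seq(0, kmax, length.out = n_bins)
  shell <- findInterval(kmag, edges, left.open = TRUE) + 1L
  shell[kmag == 0] <- 1L
  shell[shell > n_bins] <- n_bins
  power <- vapply(split(as.vector(P), shell), mean, numeric(1))
  k_lev <- c(0, (edges[-1] + edges[-length(edges)]) / 2)
  present <- as.integer(names(power))
  pw <- rep(NA_real_, n_bins)
  pw[present] <- power
  keep <- !is.na(pw)
  structure(
    list(k = k_lev[keep], power = pw[keep], peak_power = max(pw[keep])),
    class = "scattering_spectrum"
  )
}

#' @export
print.scattering_spectrum <- function(x, ...) {
  cat(sprintf(
    "<scattering_spectrum> %d radial levels, k in [0, %.3g] rad/um, peak power %.4g\n",
    length(x$k), max(x$k), x$peak_power
  ))
  invisible(x)
}

#' Half-power (3 dB) bandwidth of a scattering spectrum
#'
#' The smallest spatial frequency at which the radially averaged power first
#' drops to half its peak, linearly interpolated between adjacent radial
#' levels. If the power never falls below half-peak the maximum frequency is
#' returned with attribute `no_crossing = TRUE`.
#'
#' @param spectrum a `scattering_spectrum`, or a list with numeric `k` and
#'   `power`.
#' @return bandwidth in the units of `k` (rad/um for [compute_spectrum()]
#'   output).
#' @export
bandwidth_3db <- function(spectrum) {
  k <- spectrum$k
  p <- spectrum$power
  stopifnot(length(k) == length(p), length(k) >= 1L, all(p >= 0))
  peak <- max(p)
  if (!is.finite(peak) || peak <= 0) stop("spectrum has no positive peak")
  half <- peak / 2
  i0 <- which.max(p)
  for (i in seq(i0, length(p))) {
    if (p[i] <= half) {
      if (i == i0 || p[i] == half) return(k[i])
      # linear interpolation between (k[i-1], p[i-1]) and (k[i], p[i])
      t <- (p[i - 1] - half) / (p[i - 1] - p[i])
      return(k[i - 1] + t * (k[i] - k[i - 1]))
    }
  }
  out <- max(k)
  attr(out, "no_crossing") <- TRUE
  out
}

#' Scattering bandwidth of a nucleus arrangement
#'
#' Convenience wrapper: [build_point_model()], [compute_spectrum()],
#' [bandwidth_3db()].
#'
#' @inheritParams build_point_model
#' @param ... passed to [build_point_model()].
#' @return list with `bw3dB` and the `spectrum`.
#' @export
scattering_bandwidth <- function(centroids_um, ...) {
  spec <- compute_spectrum(build_point_model(centroids_um, ...))
  list(bw3dB = as.numeric(bandwidth_3db(spec)), spectrum = spec)
}
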