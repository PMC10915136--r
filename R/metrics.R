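#' Metric configuration
#'
#' Parameters of the similarity metrics and the combination loss. The
#' multi-scale structural-similarity exponents default to the published
#' standard weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333) over 5 dyadic
#' scales, with an 11-pixel Gaussian window (sigma 1.5) and the standard
#' stabilizers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `C3 = C2 / 2`. The
#' combination-loss weights default to (2, 1, 0.5) for the L1, MS-SSIM and
#' Pearson components.
#'
#' @param scales number of dyadic scales.
#' @param weights per-scale exponents (length `scales`); used for the
#'   contrast/structure terms at every scale and the luminance term at the
#'   top scale.
#' @param window_size,window_sigma Gaussian window parameters (pixels).
#' @param data_range value range `L` of the images.
#' @param loss_weights `(eps1, eps2, eps3)` for L1, MS-SSIM loss and
#'   Pearson loss.
#' @return a `metric_config` list.
#' @export
metric_config <- function(scales = 5L,
                          weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                          window_size = 11L, window_sigma = 1.5,
                          data_range = 1,
                          loss_weights = c(2, 1, 0.5)) {
  stopifnot(
    scales >= 1L, length(weights) >= scales, all(weights >= 0),
    window_size %% 2L == 1L, window_sigma > 0, data_range > 0,
    length(loss_weights) == 3L, all(loss_weights >= 0)
  )
  structure(
    list(
      scales = as.integer(scales), weights = weights[seq_len(scales)],
      window_size = as.integer(window_size), window_sigma = window_sigma,
      data_range = data_range, loss_weights = loss_weights
    ),
    class = "metric_config"
  )
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(range^2 / MSE)` in decibels. Identical images (`MSE = 0`)
#' return `Inf`.
#'
#' @param y,yhat numeric arrays of identical shape.
#' @param data_range value range of the data.
#' @return PSNR in dB.
#' @export
psnr <- function(y, yhat, data_range = 1) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat)) {
    stop("shape mismatch")
  }
  mse <- mean((y - yhat)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# internal: 2D separable Gaussian filtering with replicate edges, via the
# 3D kernel routine on a single-slice array
gauss2d <- function(x, size, sigma) {
  r <- (size - 1L) %/% 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  a <- array(x, c(dim(x), 1L))
  a <- .conv3d_axis(a, k, 0L)
  a <- .conv3d_axis(a, k, 1L)
  matrix(a, nrow(x), ncol(x))
}

# internal: single-scale SSIM components (luminance, contrast*structure maps)
ssim_components <- function(y, yhat, cfg) {
  L <- cfg$data_range
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  mu1 <- gauss2d(y, cfg$window_size, cfg$window_sigma)
  mu2 <- gauss2d(yhat, cfg$window_size, cfg$window_sigma)
  s11 <- gauss2d(y * y, cfg$window_size, cfg$window_sigma) - mu1^2
  s22 <- gauss2d(yhat * yhat, cfg$window_size, cfg$window_sigma) - mu2^2
  s12 <- gauss2d(y * yhat, cfg$window_size, cfg$window_sigma) - mu1 * mu2
  lum <- (2 * mu1 * mu2 + C1) / (mu1^2 + mu2^2 + C1)
  cs <- (2 * s12 + C2) / (s11 + s22 + C2) # contrast * structure combined
  list(l = mean(lum), cs = mean(cs))
}

# internal: 2x2 mean-pool downsampling
downsample2 <- function(x) {
  nr <- nrow(x) %/% 2L
  nc <- ncol(x) %/% 2L
  x <- x[seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
  0.25 * (x[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
    x[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2), drop = FALSE] +
    x[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE] +
    x[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2), drop = FALSE])
}

#' Multi-scale structural similarity
#'
#' Product of the luminance term at the coarsest scale and the combined
#' contrast/structure terms at every scale, each raised to its exponent,
#' with dyadic mean-pool downsampling between scales. The corresponding
#' loss is `1 - ms_ssim(...)`. If the images are too small for the requested
#' number of scales, the scale count is reduced with a warning (exponents
#' are renormalized to keep their sum).
#'
#' @param y,yhat numeric matrices of identical shape.
#' @param config a [metric_config()].
#' @return similarity in `[-1, 1]` (negative values arise for
#'   anti-correlated zero-mean patterns).
#' @export
ms_ssim <- function(y, yhat, config = metric_config()) {
  if (!identical(dim(y), dim(yhat))) stop("shape mismatch")
  cfg <- config
  min_dim <- min(dim(y))
  max_scales <- max(1L, floor(log2(min_dim / cfg$window_size)) + 1L)
  if (max_scales < cfg$scales) {
    warning(sprintf(
      "image too small for %d scales; using %d", cfg$scales, max_scales
    ))
    w <- cfg$weights[seq_len(max_scales)]
    cfg$weights <- w * sum(cfg$weights) / sum(w)
    cfg$scales <- max_scales
  }
  val <- 1
  sgn <- 1
  for (s in seq_len(cfg$scales)) {
    comp <- ssim_components(y, yhat, cfg)
    term <- if (s == cfg$scales) comp$l * comp$cs else comp$cs
    # negative structure terms: track the sign, exponentiate the magnitude
    sgn <- sgn * sign(term)
    val <- val * abs(term)^cfg$weights[s]
    if (s < cfg$scales) {
      y <- downsample2(y)
      yhat <- downsample2(yhat)
    }
  }
  sgn * val
}

#' Pearson correlation loss
#'
#' `(1 - r)^2` where `r` is the Pearson correlation between the flattened
#' images; 0 for perfectly (positively) correlated pairs, 4 for perfect
#' anti-correlation. Constant images have undefined correlation and raise an
#' error.
#'
#' @param y,yhat numeric arrays of identical shape.
#' @return loss in `[0, 4]`.
#' @export
pearson_loss <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat)) {
    stop("shape mismatch")
  }
  if (sd(as.vector(y)) == 0 || sd(as.vector(yhat)) == 0) {
    stop("correlation undefined for a constant image")
  }
  (1 - cor(as.vector(y), as.vector(yhat)))^2
}

#' Combination loss
#'
#' `eps1 * L1 + eps2 * (1 - MS-SSIM) + eps3 * (1 - r)^2` with default
#' weights (2, 1, 0.5); `L1` is the mean absolute error.
#'
#' @param y,yhat numeric matrices of identical shape.
#' @param config a [metric_config()].
#' @return non-negative scalar, 0 iff `y == yhat` (for non-constant
#'   images).
#' @export
combo_loss <- function(y, yhat, config = metric_config()) {
  w <- config$loss_weights
  l1 <- mean(abs(y - yhat))
  lms <- if (w[2] > 0) 1 - ms_ssim(y, yhat, config) else 0
  lpc <- if (w[3] > 0) pearson_loss(y, yhat) else 0
  w[1] * l1 + w[2] * lms + w[3] * lpc
}
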