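#' Phase volume constructor
#'
#' Wraps a 2D or 3D numeric array of optical phase values (radians) together
#' with the physical sampling metadata needed to convert integrated phase to
#' dry mass: lateral pixel size, z step, illumination wavelength and the
#' refractive increment expressed in um^3/pg.
#'
#' @param phi numeric matrix or 3D array of phase values in radians.
#' @param dx_um lateral sampling in micrometres per pixel.
#' @param dz_um axial step in micrometres per slice (ignored for 2D input).
#' @param wavelength_um illumination wavelength in micrometres.
#' @param gamma_um3_per_pg refractive increment in um^3/pg. The standard
#'   protein value 0.2 (i.e. 0.2 ml/g) is the default.
#' @return a `phase_volume` object: the array with calibration attributes.
#' @export
phase_volume <- function(phi, dx_um, dz_um = dx_um, wavelength_um = 0.488,
                         gamma_um3_per_pg = 0.2) {
  stopifnot(is.numeric(phi), length(dim(phi)) %in% c(2L, 3L) || is.matrix(phi))
  if (!all(is.finite(phi))) stop("phase field contains non-finite values")
  stopifnot(dx_um > 0, dz_um > 0, wavelength_um > 0, gamma_um3_per_pg > 0)
  structure(phi,
    dx_um = dx_um, dz_um = dz_um, wavelength_um = wavelength_um,
    gamma_um3_per_pg = gamma_um3_per_pg, class = "phase_volume"
  )
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x)
  cat(
    "<phase_volume> ", paste(d, collapse = " x "),
    sprintf(
      " | dx %.4g um, dz %.4g um, lambda %.4g um, gamma %.3g um^3/pg\n",
      attr(x, "dx_um"), attr(x, "dz_um"), attr(x, "wavelength_um"),
      attr(x, "gamma_um3_per_pg")
    )
  )
  invisible(x)
}

# internal: voxel volume in um^3 of a phase_volume
voxel_volume_um3 <- function(pv) {
  attr(pv, "dx_um")^2 * if (length(dim(pv)) == 3L) attr(pv, "dz_um") else 1
}

#' Reconstruct a phase-gradient image from four phase-shifted frames
#'
#' The interferometric acquisition records four intensity frames
#' `I_n = A + B cos(g + n*pi/2)` for `n = 0..3`, where `g` is the phase
#' gradient along the shear axis. The gradient is recovered pixelwise as
#' `atan2(I3 - I1, I0 - I2)`, in (-pi, pi].
#'
#' Pixels with zero modulation (both differences exactly zero, e.g. all four
#' frames equal) carry no gradient information; they are set to 0 and flagged
#' in the `"degenerate"` attribute mask.
#'
#' @param frames list of four numeric matrices of equal dimension, in
#'   modulator order `n = 0, 1, 2, 3`.
#' @param flip logical; negate the recovered gradient (opposite shear sign
#'   convention).
#' @return matrix of phase gradients in radians with attribute `degenerate`
#'   (logical matrix marking zero-modulation pixels).
#' @export
reconstruct_gradient <- function(frames, flip = FALSE) {
  if (!is.list(frames) || length(frames) != 4L) {
    stop("`frames` must be a list of four intensity images")
  }
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("all four frames must have identical dimensions")
  }
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1)))) {
    stop("frames contain non-finite values")
  }
  s <- frames[[4L]] - frames[[2L]] # ~ 2B sin(g)
  c_ <- frames[[1L]] - frames[[3L]] # ~ 2B cos(g)
  g <- atan2(s, c_)
  degen <- s == 0 & c_ == 0
  g[degen] <- 0
  if (flip) g <- -g
  attr(g, "degenerate") <- degen
  g
}

#' Synthesize four phase-shifted frames from a gradient field
#'
#' Forward model used for round-trip validation of [reconstruct_gradient()]:
#' `I_n = A + B cos(g + n*pi/2)`.
#'
#' @param gradient matrix of phase gradients (radians).
#' @param A,B background intensity and modulation amplitude.
#' @return list of four intensity matrices.
#' @export
synthesize_frames <- function(gradient, A = 10, B = 3) {
  lapply(0:3, function(n) A + B * cos(gradient + n * pi / 2))
}

#' Integrate a phase-gradient image along the shear axis
#'
#' Spectral inverse differentiation: each line along the shear axis is Fourier
#' transformed, divided by `i * 2 * pi * u` (`u` in cycles per sample) with
#' the DC term zeroed, and transformed back. Zeroing DC discards the mean of
#' the gradient along each line, so a constant gradient component (a ramp in
#' phase) is not recovered -- the operator is band-limited by construction.
#' The output phase is defined up to an additive constant; the global mean is
#' set to zero.
#'
#' @param gradient matrix of phase gradients in radians per pixel.
#' @param axis `"x"` (along columns, i.e. varying column index) or `"y"`
#'   (along rows); the shear direction of the acquisition.
#' @return matrix of phase values (radians), zero mean.
#' @export
integrate_gradient <- function(gradient, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!all(is.finite(gradient))) stop("gradient contains non-finite values")
  g <- if (axis == "x") t(gradient) else gradient
  n <- nrow(g)
  half <- floor(n / 2)
  u <- c(0:(n - half - 1), -half:-1) / n # standard DFT frequency layout
  denom <- 2i * pi * u
  denom[1L] <- 1 # DC handled by zeroing below
  G <- stats::mvfft(g)
  G <- G / denom
  G[1L, ] <- 0
  phi <- Re(stats::mvfft(G, inverse = TRUE)) / n
  if (axis == "x") phi <- t(phi)
  phi - mean(phi)
}
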