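#' Per-slice segmentation parameters
#'
#' Pixel-domain parameters of the per-z-section nucleus segmentation. The
#' defaults correspond to a lateral sampling of 11 pixels per micrometre;
#' passing a different `lateral_px_per_um` rescales every length/area
#' parameter proportionally (thresholds and solidity, being dimensionless,
#' are unchanged) so the same physical cut-offs apply at any sampling.
#'
#' At the reference sampling the defaults are: median window 19 px, hard
#' threshold 0.2, adaptive sensitivity 0.55 with a 145 px window, minimum
#' area 400 px^2, small-object filter at 60 px equivalent diameter (~5 um)
#' combined with solidity < 0.8.
#'
#' @param lateral_px_per_um lateral sampling the parameters should be scaled
#'   to.
#' @param median_window_px,hard_threshold,adaptive_sensitivity,adaptive_window_px,min_area_px2,min_equiv_diameter_px,min_solidity,ws_tolerance
#'   explicit overrides; lengths/areas are interpreted at the *target*
#'   sampling. `ws_tolerance` is the watershed merge tolerance (distance-map
#'   units) controlling how deep a saddle must be to split touching nuclei.
#' @return a `seg2d_params` list.
#' @export
seg2d_params <- function(lateral_px_per_um = 11,
                         median_window_px = NULL, hard_threshold = 0.2,
                         adaptive_sensitivity = 0.55,
                         adaptive_window_px = NULL, min_area_px2 = NULL,
                         min_equiv_diameter_px = NULL, min_solidity = 0.8,
                         ws_tolerance = 2, empty_fraction = 0.3) {
  s <- lateral_px_per_um / 11
  p <- list(
    lateral_px_per_um = lateral_px_per_um,
    median_window_px = median_window_px %||% odd_int(19 * s),
    hard_threshold = hard_threshold,
    adaptive_sensitivity = adaptive_sensitivity,
    adaptive_window_px = adaptive_window_px %||% odd_int(145 * s),
    min_area_px2 = min_area_px2 %||% 400 * s^2,
    min_equiv_diameter_px = min_equiv_diameter_px %||% 60 * s,
    min_solidity = min_solidity,
    ws_tolerance = ws_tolerance,
    empty_fraction = empty_fraction
  )
  stopifnot(
    p$median_window_px >= 1, p$hard_threshold >= 0, p$hard_threshold <= 1,
    p$adaptive_sensitivity >= 0, p$adaptive_sensitivity <= 1,
    p$adaptive_window_px >= 1, p$min_area_px2 > 0,
    p$min_equiv_diameter_px > 0, p$min_solidity >= 0, p$min_solidity <= 1
  )
  class(p) <- "seg2d_params"
  p
}

#' Median-filter and normalize one z-section
#'
#' Median filters the slice (square window, edge-replicated) to even out
#' intensity, then min-max normalizes to `[0, 1]`. A constant slice cannot be
#' normalized; it is returned as all zeros with attribute `empty = TRUE`.
#'
#' Median filtering commutes with monotone rescaling, so the slice is
#' affinely mapped into `[0, 1]` before filtering (required by the
#' constant-time median implementation) without changing the result.
#'
#' @param slice numeric matrix (one z-section of the nucleus channel).
#' @param params a [seg2d_params()].
#' @return numeric matrix in `[0, 1]` with attribute `empty`.
#' @export
preprocess_slice <- function(slice, params = seg2d_params()) {
  stopifnot(is.matrix(slice))
  rng <- range(slice)
  if (rng[1] == rng[2]) {
    out <- matrix(0, nrow(slice), ncol(slice))
    attr(out, "empty") <- TRUE
    return(out)
  }
  x <- (slice - rng[1]) / (rng[2] - rng[1])
  r <- (params$median_window_px - 1L) %/% 2L
  if (r >= 1L) x <- EBImage::medianFilter(x, r)
  rng2 <- range(x)
  out <- if (rng2[1] == rng2[2]) {
    matrix(0, nrow(slice), ncol(slice))
  } else {
    (x - rng2[1]) / (rng2[2] - rng2[1])
  }
  attr(out, "empty") <- rng2[1] == rng2[2]
  # dynamic range of the median-filtered slice on the original intensity
  # scale; lets stack-level callers identify background-only sections
  attr(out, "raw_range") <- diff(rng2) * (rng[2] - rng[1])
  out
}

#' Dual-threshold binarization of a normalized slice
#'
#' A pixel is foreground iff it exceeds the hard threshold *and* its local
#' adaptive threshold. The local threshold is the mean over a square window
#' (edge-replicated) scaled by `1 + (0.5 - sensitivity)`; the default
#' sensitivity 0.55 therefore makes the local criterion slightly permissive
#' (factor 0.95), and raising the sensitivity admits more foreground.
#'
#' @param norm numeric matrix in `[0, 1]` (from [preprocess_slice()]).
#' @param params a [seg2d_params()].
#' @return logical matrix.
#' @export
binarize <- function(norm, params = seg2d_params()) {
  stopifnot(is.matrix(norm), min(norm) >= 0, max(norm) <= 1)
  hw <- (params$adaptive_window_px - 1L) %/% 2L
  local_mean <- .boxmean2d(norm, hw)
  factor <- 1 + (0.5 - params$adaptive_sensitivity)
  norm > params$hard_threshold & norm > local_mean * factor
}

# internal: per-object stats for a 2D label matrix
object_table_2d <- function(lab) {
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(
      label = integer(0), cx = numeric(0), cy = numeric(0),
      area = numeric(0), solidity = numeric(0), equiv_diameter = numeric(0)
    ))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  area <- tabulate(l, nbins = n)
  sx <- vapply(split(rc[, 1], l), mean, numeric(1))
  sy <- vapply(split(rc[, 2], l), mean, numeric(1))
  keys <- as.integer(names(sx))
  cx <- cy <- sol <- rep(NA_real_, n)
  cx[keys] <- sx
  cy[keys] <- sy
  for (k in keys) {
    pts <- rc[l == k, , drop = FALSE]
    sol[k] <- area[k] / convex_area_px(pts)
  }
  keep <- area > 0
  data.frame(
    label = which(keep), cx = cx[keep], cy = cy[keep], area = area[keep],
    solidity = pmin(sol[keep], 1),
    equiv_diameter = 2 * sqrt(area[keep] / pi)
  )
}

# internal: convex hull area of a pixel set, counting pixels as unit squares.
# The hull is taken over the 4 corners of every pixel so a straight row of
# pixels has hull area equal to its pixel count (solidity 1).
convex_area_px <- function(pts) {
  if (nrow(pts) == 1L) return(1)
  corners <- rbind(
    pts + matrix(c(-0.5, -0.5), nrow(pts), 2, byrow = TRUE),
    pts + matrix(c(-0.5, 0.5), nrow(pts), 2, byrow = TRUE),
    pts + matrix(c(0.5, -0.5), nrow(pts), 2, byrow = TRUE),
    pts + matrix(c(0.5, 0.5), nrow(pts), 2, byrow = TRUE)
  )
  h <- chull(corners)
  p <- corners[h, , drop = FALSE]
  # shoelace
  xx <- p[, 1]; yy <- p[, 2]
  abs(sum(xx * c(yy[-1], yy[1]) - c(xx[-1], xx[1]) * yy)) / 2
}

#' Morphological cleanup, watershed splitting and artifact filtering
#'
#' Applies, in order: morphological opening (3x3 disc), removal of connected
#' components below the minimum area, a distance-transform watershed to
#' separate touching nuclei, and removal of post-watershed objects that are
#' *both* below the minimum equivalent diameter and below the minimum
#' solidity (small-and-ragged over-segmentation artifacts; small round polar
#' caps of genuine nuclei are kept). Surviving objects are relabelled
#' sequentially.
#'
#' @param mask logical or 0/1 matrix.
#' @param params a [seg2d_params()].
#' @return a `slice_labels` object: integer label matrix with attribute
#'   `objects`, a data frame of label, centroid (px), area (px^2), solidity
#'   and equivalent diameter (px).
#' @export
clean_and_split <- function(mask, params = seg2d_params()) {
  m <- EBImage::Image(mask * 1)
  m <- EBImage::opening(m, EBImage::makeBrush(3L, "disc"))
  lab <- EBImage::bwlabel(m)
  # pre-watershed area filter
  a <- tabulate(as.integer(lab[lab > 0]))
  drop <- which(a < params$min_area_px2)
  m <- as.matrix(lab)
  m[m %in% drop] <- 0L
  m <- m > 0L
  if (!any(m)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    attr(out, "objects") <- object_table_2d(out)
    class(out) <- c("slice_labels", class(out))
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(m * 1))
  ws <- EBImage::watershed(dm, tolerance = params$ws_tolerance, ext = 1L)
  lab <- matrix(as.integer(as.matrix(ws)), nrow(mask), ncol(mask))
  tab <- object_table_2d(lab)
  bad <- tab$label[tab$equiv_diameter < params$min_equiv_diameter_px &
    tab$solidity < params$min_solidity]
  if (length(bad)) lab[lab %in% bad] <- 0L
  # relabel sequentially in original label order
  keep <- sort(setdiff(unique(as.vector(lab)), 0L))
  relab <- integer(max(c(lab, 1L)))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  out <- lab
  attr(out, "objects") <- object_table_2d(out)
  class(out) <- c("slice_labels", class(out))
  out
}

#' Segment one nucleus-channel z-section
#'
#' Convenience wrapper running [preprocess_slice()], [binarize()] and
#' [clean_and_split()].
#'
#' @inheritParams preprocess_slice
#' @return a `slice_labels` object (see [clean_and_split()]).
#' @export
segment_slice <- function(slice, params = seg2d_params()) {
  norm <- preprocess_slice(slice, params)
  if (isTRUE(attr(norm, "empty"))) {
    out <- matrix(0L, nrow(slice), ncol(slice))
    attr(out, "objects") <- object_table_2d(out)
    class(out) <- c("slice_labels", class(out))
    return(out)
  }
  clean_and_split(binarize(norm, params), params)
}
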