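#' Dry mass of a masked region of a phase volume
#'
#' Integrates phase over a region and converts to dry mass in picograms:
#' `M = lambda / (2 * pi * gamma) * sum(phi) * voxel_volume`, with `lambda`
#' in micrometres and `gamma` in um^3/pg. Noise-dominated regions can yield a
#' negative mass; the value is returned as-is with attribute
#' `negative = TRUE`.
#'
#' @param phase a [phase_volume()].
#' @param mask logical array of the same dimensions (or voxel index vector).
#' @return dry mass in pg.
#' @export
dry_mass <- function(phase, mask) {
  stopifnot(inherits(phase, "phase_volume"))
  idx <- if (is.logical(mask)) {
    if (!identical(dim(mask), dim(phase))) stop("mask/phase shape mismatch")
    which(mask)
  } else {
    as.integer(mask)
  }
  if (length(idx) == 0L) stop("empty mask")
  m <- attr(phase, "wavelength_um") /
    (2 * pi * attr(phase, "gamma_um3_per_pg")) *
    sum(unclass(phase)[idx]) * voxel_volume_um3(phase)
  if (m < 0) attr(m, "negative") <- TRUE
  m
}

#' Volume, surface area and sphericity of a binary 3D mask
#'
#' Volume is the voxel count times the voxel volume. Surface area is the
#' area of the triangulated zero-level isosurface of the signed Euclidean
#' distance field of the mask, extracted by marching tetrahedra after a
#' light Gaussian smoothing (`smooth_sigma` voxels). The signed distance
#' field is piecewise linear across the boundary, so the level set tracks
#' the voxel boundary without the staircase overestimate of a binary
#' isosurface, and smoothing it removes discretization scalloping while
#' leaving flat faces (where the field is exactly linear) unchanged.
#' Sphericity is `pi^(1/3) * (6 V)^(2/3) / S`, i.e. the surface of the
#' equal-volume sphere over the measured surface: 1 for a perfect sphere,
#' smaller for rougher or elongated bodies.
#'
#' The mask is assumed to live on an isotropic grid. Masks touching the
#' array border are computed on a zero-padded copy and flagged with
#' attribute `touches_border`.
#'
#' @param mask logical/0-1 3D array.
#' @param voxel_size_um edge length of the (cubic) voxel in micrometres.
#' @param smooth_sigma Gaussian smoothing of the signed distance field, in
#'   voxels (0 disables).
#' @return list with `volume_um3`, `surface_um2`, `sphericity`.
#' @export
shape_features <- function(mask, voxel_size_um, smooth_sigma = 0.6) {
  stopifnot(length(dim(mask)) == 3L, voxel_size_um > 0)
  m <- (mask > 0) * 1
  nvox <- sum(m)
  if (nvox == 0L) stop("empty mask")
  V <- nvox * voxel_size_um^3
  d <- dim(m)
  touches <- any(m[1, , ] > 0) || any(m[d[1], , ] > 0) ||
    any(m[, 1, ] > 0) || any(m[, d[2], ] > 0) ||
    any(m[, , 1] > 0) || any(m[, , d[3]] > 0)
  # pad so the isosurface closes around border-touching masks
  pad <- max(3L, as.integer(ceiling(3 * smooth_sigma)) + 1L)
  mp <- array(0, dim(m) + 2L * pad)
  mp[
    pad + seq_len(d[1]), pad + seq_len(d[2]),
    pad + seq_len(d[3])
  ] <- m
  sdf <- sqrt(.edt3d_sq(mp)) - sqrt(.edt3d_sq(1 - mp))
  sdf_s <- if (smooth_sigma > 0) gaussian_blur3d(sdf, smooth_sigma) else sdf
  S_vox <- .surface_area_mt(sdf_s, 0)
  if (S_vox <= 0) {
    # tiny object smoothed away: fall back to the unsmoothed distance field
    S_vox <- .surface_area_mt(sdf, 0)
  }
  S <- S_vox * voxel_size_um^2
  out <- list(
    volume_um3 = V, surface_um2 = S,
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / S
  )
  if (touches) attr(out, "touches_border") <- TRUE
  out
}

#' Per-nucleus feature records
#'
#' Computes, for every label of an isotropic label volume co-registered with
#' a phase volume: centroid (um), volume, surface area, sphericity, dry mass
#' and dry-mass density (`rho = M / V`, stored exactly as the ratio).
#' Records with sphericity > 1 indicate under-segmented clusters and are
#' dropped; the number dropped is reported in attribute `n_dropped`.
#'
#' @param labels a [label_volume()] on an isotropic grid.
#' @param phase a [phase_volume()] of identical dimensions.
#' @param smooth_sigma passed to [shape_features()].
#' @return data frame of `nucleus_record` rows: id, cx_um, cy_um, cz_um,
#'   volume_um3, surface_um2, sphericity, dry_mass_pg, dmd_pg_per_um3.
#' @export
build_records <- function(labels, phase, smooth_sigma = 0.6) {
  stopifnot(length(dim(labels)) == 3L, inherits(phase, "phase_volume"))
  if (!identical(dim(labels)[1:3], dim(phase)[1:3])) {
    stop("labels/phase shape mismatch")
  }
  vox <- attr(labels, "dx_um")
  if (abs(attr(labels, "dz_um") - vox) > 1e-9 * vox) {
    stop("label volume is not isotropic; resample first")
  }
  idx <- which(unclass(labels) > 0L)
  empty <- data.frame(
    id = integer(0), cx_um = numeric(0), cy_um = numeric(0),
    cz_um = numeric(0), volume_um3 = numeric(0), surface_um2 = numeric(0),
    sphericity = numeric(0), dry_mass_pg = numeric(0),
    dmd_pg_per_um3 = numeric(0)
  )
  if (length(idx) == 0L) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }
  lab <- unclass(labels)[idx]
  by_label <- split(idx, lab)
  d <- dim(labels)
  lam <- attr(phase, "wavelength_um")
  gam <- attr(phase, "gamma_um3_per_pg")
  rows <- lapply(names(by_label), function(nm) {
    ii <- by_label[[nm]]
    ijk <- arrayInd(ii, d)
    # crop a bounding box for the surface mesh
    r1 <- range(ijk[, 1])
    r2 <- range(ijk[, 2])
    r3 <- range(ijk[, 3])
    sub <- array(0L, c(diff(r1), diff(r2), diff(r3)) + 1L)
    sub[cbind(ijk[, 1] - r1[1] + 1L, ijk[, 2] - r2[1] + 1L, ijk[, 3] - r3[1] + 1L)] <- 1L
    sf <- shape_features(sub, vox, smooth_sigma)
    M <- lam / (2 * pi * gam) * sum(unclass(phase)[ii]) * vox^3
    data.frame(
      id = as.integer(nm),
      cx_um = mean(ijk[, 1]) * vox, cy_um = mean(ijk[, 2]) * vox,
      cz_um = mean(ijk[, 3]) * vox,
      volume_um3 = sf$volume_um3, surface_um2 = sf$surface_um2,
      sphericity = sf$sphericity, dry_mass_pg = M,
      dmd_pg_per_um3 = M / sf$volume_um3
    )
  })
  recs <- do.call(rbind, rows)
  n_dropped <- sum(recs$sphericity > 1)
  if (n_dropped > 0) {
    message(sprintf(
      "build_records: dropped %d record(s) with sphericity > 1 (under-segmented clusters)",
      n_dropped
    ))
  }
  recs <- recs[recs$sphericity <= 1, , drop = FALSE]
  rownames(recs) <- NULL
  attr(recs, "n_dropped") <- n_dropped
  recs
}

#' Assign trophectoderm / inner-cell-mass compartments
#'
#' The embryo centre is the centroid of the nucleus centroids; each
#' nucleus's normalized radius is its distance from that centre divided by
#' the maximum distance over nuclei. Nuclei with normalized radius above the
#' threshold are labelled TE (outer shell), the rest ICM; a nucleus exactly
#' at the threshold is ICM (inclusive-inside convention). A single nucleus
#' has normalized radius 0 (ICM).
#'
#' @param records data frame from [build_records()] (needs `cx_um`, `cy_um`,
#'   `cz_um`).
#' @param threshold normalized-radius cut separating TE from ICM.
#' @return `records` with added `normalized_radius` and `compartment`
#'   columns.
#' @export
assign_compartment <- function(records, threshold = 0.7) {
  stopifnot(nrow(records) >= 1L)
  ctr <- c(mean(records$cx_um), mean(records$cy_um), mean(records$cz_um))
  dist <- sqrt((records$cx_um - ctr[1])^2 + (records$cy_um - ctr[2])^2 +
    (records$cz_um - ctr[3])^2)
  nr <- if (max(dist) > 0) dist / max(dist) else rep(0, nrow(records))
  records$normalized_radius <- nr
  records$compartment <- ifelse(nr > threshold, "TE", "ICM")
  records
}

#' Normalized mean dry-mass-density map
#'
#' Sets every voxel of each nucleus to that nucleus's mean dry-mass density,
#' Gaussian filters the volume with standard deviations `(1, 1, 3)` voxels
#' in (x, y, z), and divides by the volume maximum so values lie in
#' `[0, 1]`. An all-zero result (no records) is returned unchanged with
#' attribute `empty = TRUE`.
#'
#' @param labels a [label_volume()].
#' @param records data frame with `id` and `dmd_pg_per_um3` covering all
#'   labels present.
#' @param sigma length-3 Gaussian standard deviations in voxels.
#' @return 3D numeric array in `[0, 1]`.
#' @export
dmd_map <- function(labels, records, sigma = c(1, 1, 3)) {
  stopifnot(length(dim(labels)) == 3L)
  arr <- array(0, dim(labels))
  idx <- which(unclass(labels) > 0L)
  if (length(idx)) {
    lab <- unclass(labels)[idx]
    lut <- rep(NA_real_, max(lab))
    lut[records$id] <- records$dmd_pg_per_um3
    if (anyNA(lut[unique(lab)])) stop("records missing for some labels")
    arr[idx] <- lut[lab]
  }
  arr <- gaussian_blur3d(arr, sigma)
  mx <- max(arr)
  if (mx <= 0) {
    attr(arr, "empty") <- TRUE
    return(arr)
  }
  arr / mx
}

#' Embryo-level feature summary
#'
#' Aggregates per-nucleus records and the scattering bandwidth into the
#' embryo-level feature set used for health grading.
#'
#' @param records data frame from [build_records()] /
#'   [assign_compartment()].
#' @param bw3db half-power bandwidth from [bandwidth_3db()] (rad/um).
#' @param embryo_id identifier.
#' @param health optional known class label (`"HI"` or `"S"`).
#' @return list with `embryo_id`, `nuc_count`, `bw3dB`, `health`, `records`.
#' @export
embryo_features <- function(records, bw3db, embryo_id = NA, health = NA) {
  structure(
    list(
      embryo_id = embryo_id, nuc_count = nrow(records),
      bw3dB = as.numeric(bw3db), health = health, records = records
    ),
    class = "embryo_features"
  )
}
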