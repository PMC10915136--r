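#' 3D linking and filtering parameters
#'
#' Parameters of the trajectory-linking stage. Defaults correspond to a
#' lateral sampling of 11 pixels per micrometre and a 1 um z-step; passing a
#' different calibration rescales the pixel/voxel-domain values so the same
#' physical cut-offs apply (link radius 50 px, gap limit 5 um, volume window
#' `[5000, 250000]` voxels, minimum z-depth 3 slices, minimum extent 0.14 at
#' the reference calibration). Voxel-count filters operate in the original
#' anisotropic pixel domain, before isotropic resampling.
#'
#' @param lateral_px_per_um,z_step_um calibration of the stack the parameters
#'   will be applied to.
#' @param link_radius_px,max_gap_um,min_volume_vox,max_volume_vox,min_zdepth,min_extent,split_dip_factor
#'   explicit overrides, interpreted at the target calibration.
#'   `split_dip_factor` is the fraction of the neighbouring area maxima below
#'   which an interior area minimum qualifies as a boundary between stacked
#'   nuclei.
#' @return a `link3d_params` list.
#' @export
link3d_params <- function(lateral_px_per_um = 11, z_step_um = 1,
                          link_radius_px = NULL, max_gap_um = 5,
                          min_volume_vox = NULL, max_volume_vox = NULL,
                          min_zdepth = 3L, min_extent = 0.14,
                          split_dip_factor = 0.6) {
  s <- lateral_px_per_um / 11
  vz <- 1 / z_step_um # voxel count scales inversely with z-step
  p <- list(
    lateral_px_per_um = lateral_px_per_um, z_step_um = z_step_um,
    link_radius_px = link_radius_px %||% 50 * s,
    max_gap_um = max_gap_um,
    min_volume_vox = min_volume_vox %||% 5000 * s^2 * vz,
    max_volume_vox = max_volume_vox %||% 250000 * s^2 * vz,
    min_zdepth = as.integer(min_zdepth),
    min_extent = min_extent,
    split_dip_factor = split_dip_factor
  )
  stopifnot(
    p$link_radius_px > 0, p$max_gap_um >= 0, p$min_volume_vox > 0,
    p$max_volume_vox > p$min_volume_vox, p$min_zdepth >= 1,
    p$min_extent > 0, p$split_dip_factor > 0, p$split_dip_factor < 1
  )
  class(p) <- "link3d_params"
  p
}

#' Label volume constructor
#'
#' A 3D integer instance-label field (0 = background) with voxel size
#' metadata.
#'
#' @param arr 3D integer array of labels.
#' @param dx_um,dz_um voxel edge lengths in micrometres (lateral, axial).
#' @return a `label_volume` object.
#' @export
label_volume <- function(arr, dx_um, dz_um) {
  stopifnot(length(dim(arr)) == 3L, dx_um > 0, dz_um > 0)
  structure(arr, dx_um = dx_um, dz_um = dz_um, class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(
    "<label_volume> ", paste(dim(x), collapse = " x "),
    sprintf(
      " | %d objects | voxel %.4g x %.4g x %.4g um\n",
      length(setdiff(unique(as.vector(x)), 0L)),
      attr(x, "dx_um"), attr(x, "dx_um"), attr(x, "dz_um")
    )
  )
  invisible(x)
}

#' Link per-slice objects into z-trajectories
#'
#' Greedy nearest-centroid linking of per-slice objects across z. Candidate
#' (trajectory, object) pairs within the link radius are assigned in order of
#' increasing centroid distance, each object and trajectory at most once;
#' exact distance ties are broken in favour of the lower trajectory id.
#' Unmatched objects open new trajectories. A trajectory may bridge a gap of
#' missing slices of up to `max_gap_um`; a longer gap defines a new nuclear
#' boundary (the object restarts a trajectory). Bridged slices stay
#' background: no labels are interpolated into them.
#'
#' @param slice_labels list of `slice_labels` objects (one per z-section, in
#'   order).
#' @param params a [link3d_params()].
#' @return list of trajectories; each is a data frame with columns `z`
#'   (1-based slice index), `label` (slice label), `cx`, `cy` (px), `area`
#'   (px^2).
#' @export
link_trajectories <- function(slice_labels, params = link3d_params()) {
  stopifnot(length(slice_labels) >= 1L)
  max_gap_slices <- floor(params$max_gap_um / params$z_step_um)
  trajs <- list() # each: data.frame(z, label, cx, cy, area)
  open_last_z <- integer(0)
  for (z in seq_along(slice_labels)) {
    tab <- attr(slice_labels[[z]], "objects")
    if (is.null(tab)) tab <- object_table_2d(slice_labels[[z]])
    n_obj <- nrow(tab)
    # trajectories still eligible for extension
    eligible <- which(z - open_last_z - 1L <= max_gap_slices &
      open_last_z < z)
    assigned_obj <- rep(FALSE, n_obj)
    assigned_trj <- rep(FALSE, length(eligible))
    if (n_obj > 0L && length(eligible) > 0L) {
      last_pos <- t(vapply(trajs[eligible], function(tr) {
        c(tr$cx[nrow(tr)], tr$cy[nrow(tr)])
      }, numeric(2)))
      dmat <- outer(seq_along(eligible), seq_len(n_obj), function(i, j) {
        sqrt((last_pos[i, 1] - tab$cx[j])^2 + (last_pos[i, 2] - tab$cy[j])^2)
      })
      cand <- which(dmat <= params$link_radius_px, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dmat[cand], eligible[cand[, 1]])
        for (r in ord) {
          ti <- cand[r, 1]
          oj <- cand[r, 2]
          if (assigned_trj[ti] || assigned_obj[oj]) next
          assigned_trj[ti] <- TRUE
          assigned_obj[oj] <- TRUE
          k <- eligible[ti]
          trajs[[k]] <- rbind(trajs[[k]], data.frame(
            z = z, label = tab$label[oj], cx = tab$cx[oj], cy = tab$cy[oj],
            area = tab$area[oj]
          ))
          open_last_z[k] <- z
        }
      }
    }
    for (oj in which(!assigned_obj)) {
      trajs[[length(trajs) + 1L]] <- data.frame(
        z = z, label = tab$label[oj], cx = tab$cx[oj], cy = tab$cy[oj],
        area = tab$area[oj]
      )
      open_last_z[length(trajs)] <- z
    }
  }
  lapply(trajs, function(tr) {
    rownames(tr) <- NULL
    class(tr) <- c("nucleus_trajectory", class(tr))
    tr
  })
}

#' Split a trajectory of stacked nuclei
#'
#' Two nuclei stacked along z appear as one trajectory whose slice-area
#' profile pinches at their interface. The trajectory is split at interior
#' slices where the area is a strict local minimum, drops below
#' `split_dip_factor` times the smaller of the neighbouring local area
#' maxima, and the distance-from-first-centroid profile shows a coincident
#' boundary signal (a weak local extremum within one slice, or a step of
#' more than ~1 um across the minimum -- the signature of a laterally
#' offset stacked nucleus). A bridged axial gap of two or more empty slices
#' inside the trajectory is treated as a boundary directly. Splits that
#' would leave either side shorter than the minimum z-depth are rejected;
#' splitting recurses on the parts, so several stacked nuclei can be
#' separated.
#'
#' @param traj a trajectory data frame from [link_trajectories()].
#' @param params a [link3d_params()].
#' @return list of trajectories (length 1 if no split).
#' @export
split_stacked <- function(traj, params = link3d_params()) {
  n <- nrow(traj)
  if (n < 2L * params$min_zdepth) return(list(traj))
  # a bridged axial gap of two or more empty slices is itself a boundary:
  # a nucleus interior does not vanish from consecutive sections, whereas
  # the junction caps of stacked nuclei often fall below the 2D area
  # filter, leaving exactly such a gap (single-slice dropouts still bridge)
  gaps <- which(diff(traj$z) > 2L)
  gaps <- gaps[gaps >= params$min_zdepth & (n - gaps) >= params$min_zdepth]
  if (length(gaps)) {
    g <- gaps[which.max(diff(traj$z)[gaps])]
    return(c(
      split_stacked(traj[1:g, , drop = FALSE], params),
      split_stacked(traj[(g + 1L):n, , drop = FALSE], params)
    ))
  }
  a <- traj$area
  d <- sqrt((traj$cx - traj$cx[1])^2 + (traj$cy - traj$cy[1])^2)
  interior <- 2:(n - 1L)
  is_min <- vapply(interior, function(i) a[i] < a[i - 1] && a[i] < a[i + 1],
    logical(1)
  )
  cand <- interior[is_min]
  # weak local extrema of the distance profile (a flat profile, as for
  # coaxially stacked nuclei, qualifies everywhere; a monotone drift does not)
  d_ext <- interior[vapply(interior, function(i) {
    (d[i] <= d[i - 1] && d[i] <= d[i + 1]) ||
      (d[i] >= d[i - 1] && d[i] >= d[i + 1])
  }, logical(1))]
  # a laterally offset nucleus produces a plateau-to-plateau *step* in the
  # distance profile instead of an extremum; a jump of more than ~1 um
  # across the candidate slice is an equally valid boundary signal
  step_px <- params$lateral_px_per_um
  best <- NA_integer_
  best_depth <- Inf
  for (i in cand) {
    left_max <- max(a[1:(i - 1)])
    right_max <- max(a[(i + 1):n])
    if (a[i] >= params$split_dip_factor * min(left_max, right_max)) next
    d_step <- abs(d[min(i + 1L, n)] - d[max(i - 1L, 1L)])
    if (!any(abs(d_ext - i) <= 1L) && d_step <= step_px) next
    if ((i - 1L) < params$min_zdepth || (n - i) < params$min_zdepth) next
    if (a[i] < best_depth) {
      best <- i
      best_depth <- a[i]
    }
  }
  if (is.na(best)) return(list(traj))
  left <- traj[1:(best - 1L), , drop = FALSE]
  right <- traj[best:n, , drop = FALSE] # minimum slice goes with the lower part
  c(split_stacked(left, params), split_stacked(right, params))
}

#' Assemble trajectories into a filtered 3D label volume
#'
#' Applies [split_stacked()] to every trajectory, paints each surviving
#' trajectory's slice objects with one unique 3D label, and removes objects
#' outside the voxel-volume window, below the minimum z-depth, or below the
#' minimum extent (volume / axis-aligned bounding-box volume). The filters
#' commute: they are independent predicates on each object. Labels are
#' numbered by the z position of first appearance (ties broken by centroid
#' raster order), so a maximum z-projection yields a nucleus count map.
#'
#' @param trajectories list from [link_trajectories()].
#' @param slice_labels the list of `slice_labels` the trajectories index
#'   into.
#' @param params a [link3d_params()].
#' @return a [label_volume()] with attribute `objects`: data frame of label,
#'   voxel volume, z-depth, extent and centroid (px).
#' @export
assemble_and_filter <- function(trajectories, slice_labels,
                                params = link3d_params()) {
  dims2 <- dim(slice_labels[[1L]])
  nz <- length(slice_labels)
  trajs <- do.call(c, lapply(trajectories, split_stacked, params = params))
  keep <- list()
  for (tr in trajs) {
    vol <- sum(tr$area)
    zdepth <- length(unique(tr$z))
    if (vol < params$min_volume_vox || vol > params$max_volume_vox) next
    if (zdepth < params$min_zdepth) next
    # pixel bounding box in xy from member objects
    xr <- c(Inf, -Inf)
    yr <- c(Inf, -Inf)
    for (r in seq_len(nrow(tr))) {
      sl <- slice_labels[[tr$z[r]]]
      idx <- which(sl == tr$label[r])
      rc <- arrayInd(idx, dims2)
      xr <- range(c(xr[is.finite(xr)], rc[, 1]))
      yr <- range(c(yr[is.finite(yr)], rc[, 2]))
    }
    bbox <- (diff(xr) + 1) * (diff(yr) + 1) * (diff(range(tr$z)) + 1)
    extent <- vol / bbox
    if (extent < params$min_extent) next
    keep[[length(keep) + 1L]] <- list(
      tr = tr, vol = vol, zdepth = zdepth, extent = extent,
      first_z = min(tr$z),
      cx = sum(tr$cx * tr$area) / vol, cy = sum(tr$cy * tr$area) / vol
    )
  }
  if (length(keep)) {
    ord <- order(
      vapply(keep, `[[`, numeric(1), "first_z"),
      vapply(keep, `[[`, numeric(1), "cx"),
      vapply(keep, `[[`, numeric(1), "cy")
    )
    keep <- keep[ord]
  }
  out <- array(0L, c(dims2, nz))
  rows <- vector("list", length(keep))
  for (li in seq_along(keep)) {
    tr <- keep[[li]]$tr
    for (r in seq_len(nrow(tr))) {
      sl <- slice_labels[[tr$z[r]]]
      page <- out[, , tr$z[r]]
      page[sl == tr$label[r]] <- li
      out[, , tr$z[r]] <- page
    }
    cz <- sum(tr$z * tr$area) / keep[[li]]$vol
    rows[[li]] <- data.frame(
      label = li, volume_vox = keep[[li]]$vol, zdepth = keep[[li]]$zdepth,
      extent = keep[[li]]$extent, cx = keep[[li]]$cx, cy = keep[[li]]$cy,
      cz = cz
    )
  }
  lv <- label_volume(out,
    dx_um = 1 / params$lateral_px_per_um, dz_um = params$z_step_um
  )
  attr(lv, "objects") <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      label = integer(0), volume_vox = numeric(0), zdepth = integer(0),
      extent = numeric(0), cx = numeric(0), cy = numeric(0), cz = numeric(0)
    )
  }
  lv
}

#' Resample label and phase volumes to isotropic voxels
#'
#' Upsamples the z axis by `lateral_px_per_um * z_step_um` so voxels become
#' cubes of side `dx_um`. Output slices sit at positions `k / f` (original
#' slice units) for `k = 0 .. (nz - 1) * f`, i.e. original slices are grid
#' points and `(nz - 1) * f + 1` slices are produced. Labels use
#' nearest-neighbour interpolation (no new label values can appear); phase
#' uses linear interpolation.
#'
#' A non-integer upsampling factor is rounded to the nearest integer and the
#' effective `dz` metadata adjusted accordingly.
#'
#' @param labels a [label_volume()] (may be `NULL`).
#' @param phase a [phase_volume()] (may be `NULL`).
#' @return list with `labels` and `phase`, resampled, with updated voxel
#'   metadata.
#' @export
resample_isotropic <- function(labels = NULL, phase = NULL) {
  ref <- labels %||% phase
  if (is.null(ref)) stop("provide at least one volume")
  dx <- attr(ref, "dx_um")
  dz <- attr(ref, "dz_um")
  f <- dz / dx
  fi <- max(1L, as.integer(round(f)))
  nz <- dim(ref)[3]
  nz_out <- (nz - 1L) * fi + 1L
  pos <- (seq_len(nz_out) - 1) / fi # in original slice units, 0-based
  out <- list(labels = NULL, phase = NULL)
  if (!is.null(labels)) {
    src <- pmin(nz, pmax(1L, as.integer(round(pos)) + 1L))
    out$labels <- label_volume(labels[, , src, drop = FALSE],
      dx_um = dx, dz_um = dz / fi
    )
    attr(out$labels, "objects") <- attr(labels, "objects")
  }
  if (!is.null(phase)) {
    lo <- pmin(nz, floor(pos) + 1L)
    hi <- pmin(nz, lo + 1L)
    w <- pos - (lo - 1L)
    arr <- array(0, c(dim(phase)[1:2], nz_out))
    for (k in seq_len(nz_out)) {
      arr[, , k] <- (1 - w[k]) * phase[, , lo[k]] + w[k] * phase[, , hi[k]]
    }
    out$phase <- phase_volume(arr,
      dx_um = dx, dz_um = dz / fi,
      wavelength_um = attr(phase, "wavelength_um"),
      gamma_um3_per_pg = attr(phase, "gamma_um3_per_pg")
    )
  }
  out
}

#' Nucleus count map
#'
#' Maximum z-projection of a label volume. Because labels increase with the
#' z position of first appearance, the global maximum of the map equals the
#' number of nuclei in the volume.
#'
#' @param labels a [label_volume()] or 3D integer array.
#' @return 2D integer matrix.
#' @export
count_map <- function(labels) {
  stopifnot(length(dim(labels)) == 3L)
  apply(unclass(labels), c(1, 2), max)
}

#' Run 2D segmentation and 3D linking on a nucleus-channel stack
#'
#' End-to-end segmentation: [preprocess_slice()], [binarize()] and
#' [clean_and_split()] on every z-section, then [link_trajectories()] and
#' [assemble_and_filter()].
#'
#' Per-slice min-max normalization makes background-only sections (above and
#' below the embryo) indistinguishable from signal-bearing ones, so a
#' stack-level guard is applied first: a section whose median-filtered
#' dynamic range falls below `empty_fraction` of the largest range in the
#' stack is treated as empty and yields no objects.
#'
#' @param channel 3D array (nucleus channel).
#' @param seg_params a [seg2d_params()].
#' @param link_params a [link3d_params()].
#' @param verbose log per-stage object counts to stderr.
#' @return a [label_volume()] in the original anisotropic pixel domain.
#' @export
segment_stack <- function(channel, seg_params = seg2d_params(),
                          link_params = link3d_params(), verbose = FALSE) {
  stopifnot(length(dim(channel)) == 3L)
  norm <- lapply(seq_len(dim(channel)[3]), function(z) {
    preprocess_slice(channel[, , z], seg_params)
  })
  ranges <- vapply(norm, function(s) attr(s, "raw_range") %||% 0, numeric(1))
  min_range <- seg_params$empty_fraction * max(ranges)
  empty_map <- matrix(0L, dim(channel)[1], dim(channel)[2])
  attr(empty_map, "objects") <- object_table_2d(empty_map)
  class(empty_map) <- c("slice_labels", class(empty_map))
  slices <- lapply(seq_along(norm), function(z) {
    if (isTRUE(attr(norm[[z]], "empty")) || ranges[z] < min_range) {
      return(empty_map)
    }
    clean_and_split(binarize(norm[[z]], seg_params), seg_params)
  })
  n2d <- sum(vapply(slices, max, numeric(1)))
  trajs <- link_trajectories(slices, link_params)
  lv <- assemble_and_filter(trajs, slices, link_params)
  if (verbose) {
    message(sprintf(
      "segment_stack: %d 2D objects -> %d trajectories -> %d nuclei",
      n2d, length(trajs), nrow(attr(lv, "objects"))
    ))
  }
  lv
}
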