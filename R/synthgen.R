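#' Synthetic embryo configuration
#'
#' Builds the parameter set for [generate_embryo()]. Class presets emulate
#' day-5 embryo phenotypes: expanded blastocysts (many nuclei arranged as an
#' outer trophectoderm shell around an inner-cell-mass cluster, with a higher
#' mean nuclear dry-mass density in the shell) versus growth-arrested
#' cleavage-stage embryos (a compact ball of fewer, more frequently
#' fragmented nuclei with no shell/core density contrast). Any preset field
#' can be overridden.
#'
#' @param embryo_class one of `"blastocyst_healthy"`,
#'   `"blastocyst_intermediate"`, `"cleavage_sick"`.
#' @param n_nuclei number of nuclei (>= 1).
#' @param embryo_radius_um embryo radius in micrometres.
#' @param nucleus_radius_um_range length-2 vector `(lo, hi)` of nucleus radii
#'   in micrometres.
#' @param te_fraction fraction of nuclei placed on the outer shell
#'   (trophectoderm-like); 0 places all nuclei throughout the ball.
#' @param dmd_te_pg_per_um3,dmd_icm_pg_per_um3 mean nuclear dry-mass density
#'   (pg/um^3) for shell and core nuclei.
#' @param fragmentation_prob probability that a nucleus is rendered as a
#'   cluster of 2-4 overlapping small spheres (low sphericity).
#' @param noise_sd additive Gaussian noise (radians) on both channels.
#' @param lateral_px_per_um lateral sampling (pixels per micrometre).
#' @param z_step_um axial step in micrometres.
#' @param wavelength_um,gamma_um3_per_pg calibration used to convert density
#'   to phase via the dry-mass relation.
#' @param min_separation_um minimum surface-to-surface distance between
#'   nuclei.
#' @param cytoplasm_amplitude_rad amplitude of the smooth cytoplasmic
#'   background blob added to the phase channel only.
#' @param seed integer RNG seed; identical configs produce identical volumes.
#' @return a `synth_config` list.
#' @export
synth_config <- function(embryo_class = c(
                           "blastocyst_healthy",
                           "blastocyst_intermediate", "cleavage_sick"
                         ),
                         n_nuclei = NULL, embryo_radius_um = NULL,
                         nucleus_radius_um_range = NULL, te_fraction = NULL,
                         dmd_te_pg_per_um3 = NULL, dmd_icm_pg_per_um3 = NULL,
                         fragmentation_prob = NULL, noise_sd = 0.02,
                         lateral_px_per_um = 11, z_step_um = 1,
                         wavelength_um = 0.488, gamma_um3_per_pg = 0.2,
                         min_separation_um = 2,
                         cytoplasm_amplitude_rad = 0.01, seed = 1L) {
  embryo_class <- match.arg(embryo_class)
  preset <- switch(embryo_class,
    blastocyst_healthy = list(
      n_nuclei = 60L, embryo_radius_um = 35,
      nucleus_radius_um_range = c(2.6, 4.2), te_fraction = 0.55,
      dmd_te_pg_per_um3 = 0.0625, dmd_icm_pg_per_um3 = 0.05,
      fragmentation_prob = 0.02
    ),
    blastocyst_intermediate = list(
      n_nuclei = 45L, embryo_radius_um = 32,
      nucleus_radius_um_range = c(2.6, 4.2), te_fraction = 0.5,
      dmd_te_pg_per_um3 = 0.0625, dmd_icm_pg_per_um3 = 0.05,
      fragmentation_prob = 0.10
    ),
    cleavage_sick = list(
      n_nuclei = 22L, embryo_radius_um = 20,
      nucleus_radius_um_range = c(2.4, 3.8), te_fraction = 0,
      dmd_te_pg_per_um3 = 0.07, dmd_icm_pg_per_um3 = 0.07,
      fragmentation_prob = 0.45
    )
  )
  cfg <- list(
    embryo_class = embryo_class,
    n_nuclei = if (is.null(n_nuclei)) preset$n_nuclei else as.integer(n_nuclei),
    embryo_radius_um = embryo_radius_um %||% preset$embryo_radius_um,
    nucleus_radius_um_range =
      nucleus_radius_um_range %||% preset$nucleus_radius_um_range,
    te_fraction = te_fraction %||% preset$te_fraction,
    dmd_te_pg_per_um3 = dmd_te_pg_per_um3 %||% preset$dmd_te_pg_per_um3,
    dmd_icm_pg_per_um3 = dmd_icm_pg_per_um3 %||% preset$dmd_icm_pg_per_um3,
    fragmentation_prob = fragmentation_prob %||% preset$fragmentation_prob,
    noise_sd = noise_sd, lateral_px_per_um = lateral_px_per_um,
    z_step_um = z_step_um, wavelength_um = wavelength_um,
    gamma_um3_per_pg = gamma_um3_per_pg,
    min_separation_um = min_separation_um,
    cytoplasm_amplitude_rad = cytoplasm_amplitude_rad,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_nuclei >= 1L,
    cfg$embryo_radius_um > 0,
    length(cfg$nucleus_radius_um_range) == 2L,
    all(cfg$nucleus_radius_um_range > 0),
    max(cfg$nucleus_radius_um_range) < cfg$embryo_radius_um,
    cfg$te_fraction >= 0, cfg$te_fraction <= 1,
    cfg$dmd_te_pg_per_um3 > 0, cfg$dmd_icm_pg_per_um3 > 0,
    cfg$fragmentation_prob >= 0, cfg$fragmentation_prob <= 1,
    cfg$noise_sd >= 0, cfg$lateral_px_per_um > 0, cfg$z_step_um > 0
  )
  class(cfg) <- "synth_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: sample a point uniformly in the unit ball shell [r0, r1]
sample_shell <- function(r0, r1) {
  v <- rnorm(3)
  v <- v / sqrt(sum(v^2))
  u <- runif(1)
  r <- (r0^3 + u * (r1^3 - r0^3))^(1 / 3)
  v * r
}

# internal: place nucleus centres with rejection sampling.
# Returns data.frame(cx, cy, cz (um, embryo-centred), radius_um, compartment)
place_nuclei <- function(cfg) {
  n <- cfg$n_nuclei
  n_te <- round(cfg$te_fraction * n)
  rad <- runif(n, cfg$nucleus_radius_um_range[1], cfg$nucleus_radius_um_range[2])
  comp <- c(rep("TE", n_te), rep("ICM", n - n_te))
  R <- cfg$embryo_radius_um
  centres <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      p <- if (comp[i] == "TE") {
        sample_shell(0.80 * R, 0.92 * R)
      } else if (cfg$te_fraction > 0) {
        sample_shell(0, 0.55 * R) # ICM core inside the shell threshold
      } else {
        sample_shell(0, 0.90 * R) # undifferentiated ball
      }
      if (i == 1L) {
        ok <- TRUE
      } else {
        prev <- centres[seq_len(i - 1L), , drop = FALSE]
        dd <- sqrt(rowSums(sweep(prev, 2, p)^2))
        ok <- all(dd - rad[seq_len(i - 1L)] - rad[i] >= cfg$min_separation_um)
      }
      if (ok) {
        centres[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "placement failure: could not fit nucleus %d of %d (embryo radius %.3g um, %d tries); reduce n_nuclei or nucleus radii",
        i, n, R, 5000L
      ))
    }
  }
  data.frame(
    cx_um = centres[, 1], cy_um = centres[, 2], cz_um = centres[, 3],
    radius_um = rad, compartment = comp, stringsAsFactors = FALSE
  )
}

#' Generate one synthetic embryo
#'
#' Renders a calibrated phase volume, a nucleus-channel volume and an exact
#' ground-truth label volume from a [synth_config()]. Each nucleus is an
#' axis-aligned ellipsoid (or, with probability `fragmentation_prob`, a union
#' of 2-4 overlapping small spheres) of uniform dry-mass density `rho`; its
#' phase contribution is `2 * pi * gamma * rho / lambda` radians per voxel,
#' so integrating the noiseless phase over the nucleus support recovers its
#' dry mass exactly (up to voxelization). The phase channel additionally
#' carries a smooth low-amplitude cytoplasmic blob; both channels receive
#' independent additive Gaussian noise.
#'
#' @param config a [synth_config()].
#' @return list with elements
#'   * `phase`: [phase_volume()] (radians),
#'   * `channel`: nucleus-channel array (same grid, arbitrary intensity
#'     units proportional to nuclear density),
#'   * `labels`: ground-truth [label_volume()] (one id per nucleus),
#'   * `truth`: data frame with per-nucleus id, compartment, centroid
#'     (micrometres, embryo-centred, and pixel units), nominal radius,
#'     fragment count, rendered volume (um^3), dry mass (pg), dry-mass
#'     density (pg/um^3) and normalized radius,
#'   * `config`: the input configuration.
#' @export
generate_embryo <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_embryo_impl(config))
}

generate_embryo_impl <- function(cfg) {
  pxu <- cfg$lateral_px_per_um
  dz <- cfg$z_step_um
  placed <- place_nuclei(cfg)
  n <- nrow(placed)

  half_um <- cfg$embryo_radius_um + max(placed$radius_um) + 2
  nx <- 2L * as.integer(ceiling(half_um * pxu)) + 1L
  nz <- 2L * as.integer(ceiling(half_um / dz)) + 1L
  cx0 <- (nx + 1) / 2 # centre voxel index (1-based)
  cz0 <- (nz + 1) / 2

  phase <- array(0, c(nx, nx, nz))
  labels <- array(0L, c(nx, nx, nz))

  # per-nucleus density with mild biological variability
  dmd_mean <- ifelse(placed$compartment == "TE",
    cfg$dmd_te_pg_per_um3, cfg$dmd_icm_pg_per_um3
  )
  rho <- pmax(dmd_mean * (1 + 0.05 * rnorm(n)), 0.2 * dmd_mean)
  phi_per_voxel <- 2 * pi * cfg$gamma_um3_per_pg * rho / cfg$wavelength_um

  fragmented <- runif(n) < cfg$fragmentation_prob
  n_frag <- ifelse(fragmented, sample(2:4, n, replace = TRUE), 1L)

  # spheres making up each nucleus: centre (um) + radius (um) + axis scales
  for (i in seq_len(n)) {
    ctr <- as.numeric(placed[i, c("cx_um", "cy_um", "cz_um")])
    r <- placed$radius_um[i]
    if (fragmented[i]) {
      # connected chain of small spheres inside the nominal radius: touching
      # but extended, so the union surface pinches at the necks and the
      # cluster sphericity drops well below an intact nucleus
      repeat {
        rads <- r * runif(n_frag[i], 0.40, 0.52)
        offs <- t(vapply(seq_len(n_frag[i]), function(j) {
          sample_shell(if (j == 1) 0 else 0.25 * r, (1 - max(rads) / r) * r)
        }, numeric(3)))
        dd <- as.matrix(dist(offs))
        touching <- dd < outer(rads, rads, "+")
        # union connected? breadth-first over the touching graph
        seen <- c(1L)
        repeat {
          nb <- which(apply(touching[seen, , drop = FALSE], 2, any))
          if (length(setdiff(nb, seen)) == 0L) break
          seen <- union(seen, nb)
        }
        if (length(seen) == n_frag[i]) break
      }
      parts <- lapply(seq_len(n_frag[i]), function(j) {
        list(c = ctr + offs[j, ], ax = rep(rads[j], 3))
      })
    } else {
      ax <- r * runif(3, 0.92, 1.08)
      parts <- list(list(c = ctr, ax = ax))
    }
    for (p in parts) {
      # bounding box in voxel indices
      i0 <- max(1L, floor(cx0 + (p$c[1] - p$ax[1]) * pxu))
      i1 <- min(nx, ceiling(cx0 + (p$c[1] + p$ax[1]) * pxu))
      j0 <- max(1L, floor(cx0 + (p$c[2] - p$ax[2]) * pxu))
      j1 <- min(nx, ceiling(cx0 + (p$c[2] + p$ax[2]) * pxu))
      k0 <- max(1L, floor(cz0 + (p$c[3] - p$ax[3]) / dz))
      k1 <- min(nz, ceiling(cz0 + (p$c[3] + p$ax[3]) / dz))
      xs <- ((i0:i1) - cx0) / pxu
      ys <- ((j0:j1) - cx0) / pxu
      zs <- ((k0:k1) - cz0) * dz
      q <- outer(
        outer((xs - p$c[1])^2 / p$ax[1]^2, (ys - p$c[2])^2 / p$ax[2]^2, "+"),
        (zs - p$c[3])^2 / p$ax[3]^2, "+"
      )
      inside <- q <= 1
      sub <- labels[i0:i1, j0:j1, k0:k1]
      sub[inside] <- i
      labels[i0:i1, j0:j1, k0:k1] <- sub
      subp <- phase[i0:i1, j0:j1, k0:k1]
      subp[inside] <- phi_per_voxel[i]
      phase[i0:i1, j0:j1, k0:k1] <- subp
    }
  }

  channel <- phase # nuclear contribution only, before cytoplasm

  # smooth cytoplasmic background (phase channel only): a super-Gaussian
  # plateau, nearly uniform inside the embryo with a soft boundary, so the
  # background adds no artificial radial density gradient between shell
  # (TE) and core (ICM) nuclei
  if (cfg$cytoplasm_amplitude_rad > 0) {
    xs <- ((seq_len(nx)) - cx0) / pxu
    zs <- ((seq_len(nz)) - cz0) * dz
    rr <- outer(outer(xs^2, xs^2, "+"), zs^2, "+")
    phase <- phase + cfg$cytoplasm_amplitude_rad *
      exp(-(rr / (1.05 * cfg$embryo_radius_um)^2)^4)
  }

  if (cfg$noise_sd > 0) {
    phase <- phase + array(rnorm(length(phase), 0, cfg$noise_sd), dim(phase))
    channel <- channel +
      array(rnorm(length(channel), 0, cfg$noise_sd), dim(channel))
  }

  # exact ground truth from the rendered label field
  vox_um3 <- dz / pxu^2
  idx <- which(labels > 0L)
  lab <- labels[idx]
  ijk <- arrayInd(idx, dim(labels))
  vox_count <- tabulate(lab, nbins = n)
  cx_px <- vapply(split(ijk[, 1], lab), mean, numeric(1))[as.character(seq_len(n))]
  cy_px <- vapply(split(ijk[, 2], lab), mean, numeric(1))[as.character(seq_len(n))]
  cz_sl <- vapply(split(ijk[, 3], lab), mean, numeric(1))[as.character(seq_len(n))]
  truth <- data.frame(
    id = seq_len(n),
    compartment = placed$compartment,
    cx_um = (cx_px - cx0) / pxu, cy_um = (cy_px - cx0) / pxu,
    cz_um = (cz_sl - cz0) * dz,
    cx_px = cx_px, cy_px = cy_px, cz_slice = cz_sl,
    radius_um = placed$radius_um,
    n_fragments = n_frag,
    volume_um3 = vox_count * vox_um3,
    dry_mass_pg = rho * vox_count * vox_um3,
    dmd_pg_per_um3 = rho,
    stringsAsFactors = FALSE
  )
  ctr <- c(mean(truth$cx_um), mean(truth$cy_um), mean(truth$cz_um))
  d <- sqrt((truth$cx_um - ctr[1])^2 + (truth$cy_um - ctr[2])^2 +
    (truth$cz_um - ctr[3])^2)
  truth$normalized_radius <- if (max(d) > 0) d / max(d) else rep(0, n)

  list(
    phase = phase_volume(phase,
      dx_um = 1 / pxu, dz_um = dz,
      wavelength_um = cfg$wavelength_um,
      gamma_um3_per_pg = cfg$gamma_um3_per_pg
    ),
    channel = structure(channel, dx_um = 1 / pxu, dz_um = dz),
    labels = label_volume(labels, dx_um = 1 / pxu, dz_um = dz),
    truth = truth,
    config = cfg
  )
}

#' Generate a synthetic embryo cohort manifest
#'
#' Derives per-embryo configurations (class, nucleus count, seed) from a
#' master seed. Class counts follow largest-remainder rounding of
#' `class_mix * n_embryos`. Per-embryo nucleus counts are drawn from
#' class-specific normal distributions (healthy 60 +/- 8 clamped to
#' `[45, 80]`, intermediate 45 +/- 8 in `[30, 65]`, sick 22 +/- 5 in
#' `[12, 32]`) so that arrested embryos carry fewer nuclei on average.
#'
#' @param n_embryos number of embryos (>= 1).
#' @param class_mix named or ordered numeric vector of proportions for
#'   (healthy, intermediate, sick); must sum to 1.
#' @param seed master seed; all per-embryo seeds derive from it.
#' @param materialize if `TRUE`, also generate the embryo volumes (memory
#'   heavy); otherwise return the manifest and configs only.
#' @param ... overrides passed to every [synth_config()] call (e.g.
#'   `lateral_px_per_um`, `noise_sd`).
#' @return list with `manifest` (data frame: embryo_id, class, label in
#'   H/I/S, health in HI/S, n_nuclei, seed), `configs` (list of
#'   [synth_config()]), and if materialized, `embryos` (list of
#'   [generate_embryo()] results).
#' @export
generate_cohort <- function(n_embryos,
                            class_mix = c(
                              blastocyst_healthy = 0.4,
                              blastocyst_intermediate = 0.3,
                              cleavage_sick = 0.3
                            ),
                            seed = 1L, materialize = FALSE, ...) {
  if (n_embryos < 1L) stop("n_embryos must be >= 1")
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  classes <- c("blastocyst_healthy", "blastocyst_intermediate", "cleavage_sick")
  if (!is.null(names(class_mix))) class_mix <- class_mix[classes]
  # largest-remainder apportionment
  raw <- class_mix * n_embryos
  cnt <- floor(raw)
  rem <- n_embryos - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  cls <- rep(classes, times = cnt)

  spec <- list(
    blastocyst_healthy = c(60, 8, 45, 80),
    blastocyst_intermediate = c(45, 8, 30, 65),
    cleavage_sick = c(22, 5, 12, 32)
  )
  n_nuc <- with_seed(seed, {
    vapply(cls, function(cl) {
      s <- spec[[cl]]
      as.integer(min(max(round(rnorm(1, s[1], s[2])), s[3]), s[4]))
    }, integer(1))
  })
  sub_seed <- (as.numeric(seed) * 1009 + 7919 * seq_len(n_embryos)) %% 2147483647
  manifest <- data.frame(
    embryo_id = seq_len(n_embryos),
    class = cls,
    label = c(
      blastocyst_healthy = "H", blastocyst_intermediate = "I",
      cleavage_sick = "S"
    )[cls],
    health = ifelse(cls == "cleavage_sick", "S", "HI"),
    n_nuclei = n_nuc,
    seed = as.integer(sub_seed),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # embryo radius grows with the cube root of the nucleus count so cohort
  # draws keep a constant packing density and always fit their shell/core
  dots <- list(...)
  configs <- lapply(seq_len(n_embryos), function(i) {
    cl_args <- c(
      list(embryo_class = cls[i], n_nuclei = n_nuc[i], seed = manifest$seed[i]),
      dots
    )
    if (!("embryo_radius_um" %in% names(dots))) {
      s <- spec[[cls[i]]]
      base_r <- switch(cls[i],
        blastocyst_healthy = 35, blastocyst_intermediate = 32,
        cleavage_sick = 20
      )
      cl_args$embryo_radius_um <- base_r * (n_nuc[i] / s[1])^(1 / 3)
    }
    do.call(synth_config, cl_args)
  })
  out <- list(manifest = manifest, configs = configs)
  if (materialize) out$embryos <- lapply(configs, generate_embryo)
  out
}
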