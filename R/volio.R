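#' Read a multi-page TIFF stack
#'
#' Reads a z-stack written by [write_stack()] (or any multi-page TIFF with
#' equal page sizes). If a JSON sidecar (`<path>.json`) is present, the
#' affine intensity scaling recorded there is inverted and any calibration
#' metadata restored; label stacks are mapped back to integers.
#'
#' @param path TIFF file path.
#' @return 3D array; for `kind = "label"` sidecars an integer array. Stored
#'   calibration appears as `dx_um`/`dz_um` (and wavelength/gamma)
#'   attributes.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
    error = function(e) stop("unreadable TIFF '", path, "': ", conditionMessage(e))
  )
  if (!length(pages)) stop("empty TIFF: ", path)
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1)))) {
    stop("inconsistent page sizes in ", path)
  }
  # TIFF rows are y; store as [x, y, z]
  arr <- array(0, c(d1[2L], d1[1L], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    arr <- arr * meta$scale + meta$offset
    if (identical(meta$kind, "label")) {
      arr <- array(as.integer(round(arr)), dim(arr))
    }
    for (at in c("dx_um", "dz_um", "wavelength_um", "gamma_um3_per_pg")) {
      if (!is.null(meta[[at]])) attr(arr, at) <- meta[[at]]
    }
  }
  arr
}

#' Write a volume as a multi-page TIFF stack
#'
#' One page per z-section. The TIFF library stores samples in `[0, 1]`, so
#' the volume is affinely mapped into that range and the inverse transform
#' (together with calibration metadata and the stack kind) is recorded in a
#' JSON sidecar `<path>.json`, which [read_stack()] applies on load. Phase
#' and other real-valued stacks use 32-bit samples (quantization about 1e-9
#' of the dynamic range); label stacks use 16 bits and round-trip exactly.
#'
#' @param vol 3D array (or object with calibration attributes such as
#'   [phase_volume()] / [label_volume()]).
#' @param path output TIFF path.
#' @param kind `"float"` or `"label"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(vol, path, kind = c("float", "label")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(vol)) == 3L)
  v <- unclass(vol)
  attrs <- attributes(v)[c("dx_um", "dz_um", "wavelength_um", "gamma_um3_per_pg")]
  if (kind == "label") {
    mx <- max(v)
    if (mx > 65535) stop("more than 65535 labels")
    offset <- 0
    scale <- max(mx, 1L)
    bits <- 16L
  } else {
    rng <- range(v)
    offset <- rng[1L]
    scale <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
    bits <- 32L
  }
  pages <- lapply(seq_len(dim(v)[3L]), function(k) {
    t((v[, , k] - offset) / scale)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- c(
    list(kind = kind, offset = offset, scale = scale, bits = bits),
    Filter(Negate(is.null), attrs)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles calibration, stage parameters and output settings for
#' [run_pipeline()]; serializable to YAML with [write_config()] /
#' [read_config()].
#'
#' @param lateral_px_per_um,z_step_um,wavelength_um,gamma_um3_per_pg
#'   acquisition calibration.
#' @param seg passed to [seg2d_params()] (the calibration is filled in).
#' @param link passed to [link3d_params()].
#' @param scatter_grid FFT lattice size for the scattering spectrum.
#' @param compartment_threshold normalized-radius TE/ICM cut.
#' @param fbm_model optional path to a serialized FBM model for grading.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(lateral_px_per_um = 11, z_step_um = 1,
                            wavelength_um = 0.488, gamma_um3_per_pg = 0.2,
                            seg = list(), link = list(), scatter_grid = 256L,
                            compartment_threshold = 0.7, fbm_model = NULL,
                            out_dir = ".", seed = 1L) {
  cfg <- list(
    lateral_px_per_um = lateral_px_per_um, z_step_um = z_step_um,
    wavelength_um = wavelength_um, gamma_um3_per_pg = gamma_um3_per_pg,
    seg = seg, link = link, scatter_grid = as.integer(scatter_grid),
    compartment_threshold = compartment_threshold,
    fbm_model = fbm_model, out_dir = out_dir, seed = as.integer(seed)
  )
  stopifnot(
    cfg$lateral_px_per_um > 0, cfg$z_step_um > 0, cfg$wavelength_um > 0,
    cfg$gamma_um3_per_pg > 0, cfg$scatter_grid >= 16L,
    cfg$compartment_threshold >= 0, cfg$compartment_threshold <= 1
  )
  if (!is.null(cfg$fbm_model) && !file.exists(cfg$fbm_model)) {
    stop("fbm_model file does not exist: ", cfg$fbm_model)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

#' Extract embryo-level features from a segmented volume
#'
#' Resamples the label and phase volumes to isotropic voxels, builds
#' per-nucleus records, assigns TE/ICM compartments and computes the
#' scattering bandwidth of the centroid arrangement.
#'
#' @param labels anisotropic [label_volume()] (e.g. from
#'   [segment_stack()] or ground truth).
#' @param phase matching [phase_volume()].
#' @param scatter_grid FFT lattice size.
#' @param compartment_threshold TE/ICM normalized-radius cut.
#' @param embryo_id,health passed through to [embryo_features()].
#' @return an `embryo_features` object.
#' @export
analyze_embryo <- function(labels, phase, scatter_grid = 256L,
                           compartment_threshold = 0.7, embryo_id = NA,
                           health = NA) {
  iso <- resample_isotropic(labels, phase)
  recs <- build_records(iso$labels, iso$phase)
  if (nrow(recs) == 0L) {
    return(embryo_features(recs, NA_real_, embryo_id, health))
  }
  recs <- assign_compartment(recs, compartment_threshold)
  extent <- dim(iso$labels) * attr(iso$labels, "dx_um")
  bw <- scattering_bandwidth(
    as.matrix(recs[, c("cx_um", "cy_um", "cz_um")]),
    extent_um = extent, grid = scatter_grid
  )
  ef <- embryo_features(recs, bw$bw3dB, embryo_id, health)
  ef$spectrum <- bw$spectrum
  ef
}

# internal: per-nucleus rows augmented with the embryo-level features, in
# the classifier's input layout
fbm_rows <- function(ef) {
  recs <- ef$records
  data.frame(
    embryo_id = ef$embryo_id, bw3dB = ef$bw3dB, nuc_count = ef$nuc_count,
    dmd_pg_per_um3 = recs$dmd_pg_per_um3, surface_um2 = recs$surface_um2,
    sphericity = recs$sphericity,
    health = ef$health, stringsAsFactors = FALSE
  )
}

#' Run the full analysis pipeline on one embryo
#'
#' Segments the nucleus-channel stack, extracts per-nucleus and
#' embryo-level features, and writes per-embryo outputs into
#' `config$out_dir`: `features.csv`, `spectrum.csv`, `summary.json`,
#' `labels.tif`, `count_map.tif` and `dmd_map.tif`. If the configuration
#' names an FBM model, the embryo is graded by max-voting and the grade
#' stored in the summary.
#'
#' @param phase_path,channel_path multi-page TIFF paths (phase in radians;
#'   nucleus channel), or in-memory arrays.
#' @param config a [pipeline_config()].
#' @param embryo_id identifier used in file names and the summary.
#' @return the `embryo_features` object, invisibly; side effect: files
#'   under `config$out_dir/embryo_id/`.
#' @export
run_pipeline <- function(phase_path, channel_path,
                         config = pipeline_config(), embryo_id = "embryo") {
  t0 <- proc.time()[["elapsed"]]
  load_vol <- function(x) if (is.character(x)) read_stack(x) else x
  phase_arr <- load_vol(phase_path)
  channel <- load_vol(channel_path)
  if (!identical(dim(phase_arr)[1:3], dim(channel)[1:3])) {
    stop("phase and channel stacks have different dimensions")
  }
  phase <- phase_volume(unclass(phase_arr) + 0,
    dx_um = 1 / config$lateral_px_per_um, dz_um = config$z_step_um,
    wavelength_um = config$wavelength_um,
    gamma_um3_per_pg = config$gamma_um3_per_pg
  )
  seg_p <- do.call(seg2d_params, c(
    list(lateral_px_per_um = config$lateral_px_per_um), config$seg
  ))
  link_p <- do.call(link3d_params, c(
    list(
      lateral_px_per_um = config$lateral_px_per_um,
      z_step_um = config$z_step_um
    ), config$link
  ))
  labels <- segment_stack(channel, seg_p, link_p, verbose = TRUE)
  ef <- analyze_embryo(labels, phase,
    scatter_grid = config$scatter_grid,
    compartment_threshold = config$compartment_threshold,
    embryo_id = embryo_id
  )

  dir <- file.path(config$out_dir, embryo_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- ef$records
  write.csv(format_num_df(recs), file.path(dir, "features.csv"),
    row.names = FALSE, quote = FALSE
  )
  if (!is.null(ef$spectrum)) {
    write.csv(
      format_num_df(data.frame(k = ef$spectrum$k, power = ef$spectrum$power)),
      file.path(dir, "spectrum.csv"),
      row.names = FALSE, quote = FALSE
    )
  }
  write_stack(labels, file.path(dir, "labels.tif"), kind = "label")
  cm <- count_map(labels)
  write_stack(array(cm, c(dim(cm), 1L)), file.path(dir, "count_map.tif"),
    kind = "label"
  )
  if (nrow(recs)) {
    iso <- resample_isotropic(labels = labels)
    write_stack(dmd_map(iso$labels, recs), file.path(dir, "dmd_map.tif"))
  }
  summary <- list(
    embryo_id = embryo_id, nuc_count = ef$nuc_count, bw3dB = ef$bw3dB,
    n_te = sum(recs$compartment == "TE"),
    n_icm = sum(recs$compartment == "ICM"),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)
  )
  if (!is.null(config$fbm_model) && nrow(recs)) {
    model <- read_fbm(config$fbm_model)
    grade <- max_vote(predict_items(model, fbm_rows(ef)))
    summary$grade <- list(
      class = grade$class, cp = grade$cp,
      majority_fraction = grade$majority_fraction, tie = grade$tie
    )
    ef$grade <- grade
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
    digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(ef)
}

# internal: pin floating point formatting so repeated runs are byte-stable
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- formatC(df[[nm]], digits = 10, format = "g")
  }
  df
}

#' Extract grading features for a synthetic cohort
#'
#' Generates each embryo of a [generate_cohort()] manifest and computes its
#' feature set with [analyze_embryo()], using the generator's exact
#' ground-truth instance labels (segmentation fidelity is assessed
#' separately). Embryos are processed one at a time so cohort size is not
#' memory-bound.
#'
#' @param cohort a [generate_cohort()] result (manifest + configs).
#' @param scatter_grid FFT lattice size for the scattering bandwidth.
#' @param compartment_threshold TE/ICM normalized-radius cut.
#' @return list with `rows` (per-nucleus classifier rows across the cohort,
#'   with `embryo_id` and true `health`) and `records` (per-embryo list of
#'   compartment-annotated nucleus records).
#' @export
extract_cohort_features <- function(cohort, scatter_grid = 128L,
                                    compartment_threshold = 0.7) {
  rows <- vector("list", nrow(cohort$manifest))
  records <- vector("list", nrow(cohort$manifest))
  for (i in seq_len(nrow(cohort$manifest))) {
    e <- generate_embryo(cohort$configs[[i]])
    ef <- suppressMessages(analyze_embryo(
      e$labels, e$phase,
      scatter_grid = scatter_grid,
      compartment_threshold = compartment_threshold,
      embryo_id = cohort$manifest$embryo_id[i],
      health = cohort$manifest$health[i]
    ))
    rows[[i]] <- fbm_rows(ef)
    records[[i]] <- ef$records
  }
  list(rows = do.call(rbind, rows), records = records)
}

#' Class-frequency-weighted F1 score
#'
#' Per-class F1 scores weighted by the true class frequencies; the weighting
#' emphasises performance on the majority class of an imbalanced test set.
#'
#' @param truth,predicted class label vectors.
#' @return weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, predicted) {
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  w <- vapply(classes, function(cl) mean(truth == cl), numeric(1))
  sum(f1 * w)
}
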