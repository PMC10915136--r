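# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# digitized sphere mask of radius r (voxels), centred, with margin
digitized_sphere <- function(r_vox, margin = 3L) {
  n <- 2L * ceiling(r_vox) + 2L * margin + 1L
  ax <- seq_len(n) - (n + 1) / 2
  outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= r_vox^2
}

# filled disc image (matrix) of radius r at centre (cx, cy)
disc_image <- function(nrow, ncol, cx, cy, r, value = 1) {
  d2 <- outer((seq_len(nrow) - cx)^2, (seq_len(ncol) - cy)^2, "+")
  (d2 <= r^2) * value
}

# a small healthy blastocyst generated on a near-isotropic grid; reused by
# feature / compartment / pipeline tests
small_blastocyst <- function() {
  fixture("small_blastocyst", function() {
    generate_embryo(synth_config("blastocyst_healthy",
      lateral_px_per_um = 2.5, z_step_um = 0.4, seed = 42
    ))
  })
}

# fabricate a slice_labels object from an objects table (for trajectory
# linking tests that only need centroids/areas)
fake_slice <- function(objects, dims = c(64L, 64L)) {
  m <- matrix(0L, dims[1], dims[2])
  attr(m, "objects") <- objects
  class(m) <- c("slice_labels", class(m))
  m
}

fake_objects <- function(cx, cy, area = rep(100, length(cx))) {
  data.frame(
    label = seq_along(cx), cx = cx, cy = cy, area = area,
    solidity = rep(1, length(cx)), equiv_diameter = 2 * sqrt(area / pi)
  )
}

# paint a label image stack from per-slice discs: list of data.frames
# (cx, cy, r) -> list of slice_labels with computed object tables
painted_stack <- function(per_slice, dims) {
  lapply(per_slice, function(df) {
    m <- matrix(0L, dims[1], dims[2])
    if (nrow(df)) {
      for (i in seq_len(nrow(df))) {
        m[disc_image(dims[1], dims[2], df$cx[i], df$cy[i], df$r[i]) > 0] <- i
      }
    }
    attr(m, "objects") <- embryoqp:::object_table_2d(m)
    class(m) <- c("slice_labels", class(m))
    m
  })
}

# separable 2-class nucleus-feature table mirroring the synthetic cohort
# structure (healthy: many nuclei, low bandwidth; sick: few, high bandwidth)
toy_feature_table <- function(n_per_class, seed = 1) {
  set.seed(seed)
  hi <- data.frame(
    bw3dB = rnorm(n_per_class, 0.06, 0.01),
    nuc_count = round(rnorm(n_per_class, 60, 8)),
    dmd_pg_per_um3 = rnorm(n_per_class, 0.060, 0.005),
    surface_um2 = rnorm(n_per_class, 150, 20),
    sphericity = rnorm(n_per_class, 0.99, 0.01),
    health = "HI"
  )
  s <- data.frame(
    bw3dB = rnorm(n_per_class, 0.10, 0.012),
    nuc_count = round(rnorm(n_per_class, 18, 5)),
    dmd_pg_per_um3 = rnorm(n_per_class, 0.076, 0.006),
    surface_um2 = rnorm(n_per_class, 95, 15),
    sphericity = rnorm(n_per_class, 0.95, 0.03),
    health = "S"
  )
  rbind(hi, s)
}

# grading cohort: 80 embryos (stratified into 40 train / 10 validation /
# 30 test downstream), features from ground-truth instance labels
grading_cohort <- function() {
  fixture("grading_cohort", function() {
    co <- generate_cohort(80,
      seed = 101,
      lateral_px_per_um = 2.5, z_step_um = 0.4
    )
    feats <- extract_cohort_features(co, scatter_grid = 128L)
    list(manifest = co$manifest, rows = feats$rows, records = feats$records)
  })
}

# stratified train/validation/test embryo split of the grading cohort
grading_split <- function(manifest, seed = 11) {
  set.seed(seed)
  out <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (ids in split(manifest$embryo_id, manifest$health)) {
    ids <- sample(ids)
    n <- length(ids)
    n_tr <- round(0.5 * n) # 40 / 10 / 30 proportions out of 80
    n_va <- round(0.125 * n)
    out$train <- c(out$train, ids[seq_len(n_tr)])
    out$valid <- c(out$valid, ids[n_tr + seq_len(n_va)])
    out$test <- c(out$test, ids[(n_tr + n_va + 1):n])
  }
  lapply(out, sort)
}

# segmentation-recovery cohort: 30 embryos, mixed classes, intact nuclei
seg_recovery <- function() {
  fixture("seg_recovery", function() {
    co <- generate_cohort(30,
      seed = 202,
      lateral_px_per_um = 4, z_step_um = 1, fragmentation_prob = 0
    )
    sp <- seg2d_params(lateral_px_per_um = 4)
    lp <- link3d_params(lateral_px_per_um = 4, z_step_um = 1)
    exact <- logical(30)
    cent_err <- numeric(30)
    for (i in 1:30) {
      e <- generate_embryo(co$configs[[i]])
      lv <- segment_stack(unclass(e$channel), sp, lp)
      obj <- attr(lv, "objects")
      tr <- e$truth
      exact[i] <- nrow(obj) == nrow(tr)
      if (nrow(obj)) {
        errs <- vapply(seq_len(nrow(obj)), function(j) {
          min(sqrt(((obj$cx[j] - tr$cx_px) / 4)^2 +
            ((obj$cy[j] - tr$cy_px) / 4)^2 +
            ((obj$cz[j] - tr$cz_slice) * 1)^2))
        }, numeric(1))
        cent_err[i] <- mean(errs)
      } else {
        cent_err[i] <- NA_real_
      }
    }
    list(manifest = co$manifest, exact = exact, cent_err = cent_err)
  })
}

# train the grader on the 40/10 train/validation embryos and predict the
# 30 held-out test embryos; cached for the grading and sparse-vote checks
grading_eval <- function() {
  fixture("grading_eval", function() {
    gc <- grading_cohort()
    sp <- grading_split(gc$manifest)
    rows <- gc$rows
    in_tr <- rows$embryo_id %in% c(sp$train, sp$valid)
    model <- train_fbm(
      rows[in_tr, ], rows$health[in_tr],
      validation = which(rows$embryo_id[in_tr] %in% sp$valid), seed = 7
    )
    test_rows <- rows[rows$embryo_id %in% sp$test, ]
    pred <- predict_items(model, test_rows)
    per_embryo <- do.call(rbind, lapply(sp$test, function(id) {
      sel <- test_rows$embryo_id == id
      g <- max_vote(pred[sel, ])
      data.frame(
        embryo_id = id, truth = unique(test_rows$health[sel]),
        graded = g$class, cp = g$cp,
        nucleus_acc = mean(pred$class[sel] == test_rows$health[sel])
      )
    }))
    list(
      model = model, test_rows = test_rows, pred = pred,
      per_embryo = per_embryo,
      nucleus_acc = mean(pred$class == test_rows$health),
      embryo_acc = mean(per_embryo$graded == per_embryo$truth)
    )
  })
}
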