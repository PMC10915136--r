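test_that("dry mass matches the closed form and is additive over disjoint masks", {
  phi <- array(0, c(12, 12, 12))
  maskA <- array(FALSE, dim(phi))
  maskA[1:5, 1:5, 1:4] <- TRUE # 100 voxels of 1 um^3
  phi[maskA] <- 1
  pv <- phase_volume(phi, dx_um = 1, dz_um = 1) # lambda 0.488, gamma 0.2
  expect_equal(as.numeric(dry_mass(pv, maskA)), 0.488 * 100 / (2 * pi * 0.2),
    tolerance = 1e-12
  )
  expect_equal(as.numeric(dry_mass(pv, array(TRUE, dim(phi)) & phi == 0)), 0)
  maskB <- array(FALSE, dim(phi))
  maskB[8:10, 8:10, 8:10] <- TRUE
  phi[maskB] <- 0.5
  pv <- phase_volume(phi, dx_um = 1, dz_um = 1)
  expect_equal(
    as.numeric(dry_mass(pv, maskA | maskB)),
    as.numeric(dry_mass(pv, maskA)) + as.numeric(dry_mass(pv, maskB))
  )
  expect_error(dry_mass(pv, array(FALSE, dim(phi))), "empty mask")
})

test_that("negative (noise-dominated) dry mass is flagged", {
  phi <- array(-0.1, c(4, 4, 4))
  pv <- phase_volume(phi, 1, 1)
  m <- dry_mass(pv, array(TRUE, dim(phi)))
  expect_lt(m, 0)
  expect_true(isTRUE(attr(m, "negative")))
})

test_that("shape oracles: digitized sphere and voxel cube", {
  # radius 10 um sphere sampled at 0.25 um voxels
  sf <- shape_features(digitized_sphere(40), voxel_size_um = 0.25)
  expect_lt(abs(sf$volume_um3 / (4 / 3 * pi * 10^3) - 1), 0.02)
  expect_gt(sf$sphericity, 0.95)
  expect_lt(sf$sphericity, 1.02)
  # voxel cube: ideal sphericity (pi/6)^(1/3) ~ 0.806; the smoothed
  # signed-distance mesh rounds corners, so allow the mesh tolerance
  cu <- array(0, c(30, 30, 30))
  cu[6:25, 6:25, 6:25] <- 1
  sfc <- shape_features(cu, 1)
  expect_equal(sfc$volume_um3, 8000)
  expect_lt(abs(sfc$sphericity - (pi / 6)^(1 / 3)), 0.06)
  # single voxel: volume exact, surface finite
  one <- array(0, c(5, 5, 5))
  one[3, 3, 3] <- 1
  sfo <- shape_features(one, 1)
  expect_equal(sfo$volume_um3, 1)
  expect_true(is.finite(sfo$sphericity))
})

test_that("per-nucleus records recover ground-truth density and drop Sp > 1", {
  e <- fixture("records_embryo", function() {
    generate_embryo(synth_config("blastocyst_healthy",
      n_nuclei = 12, embryo_radius_um = 18, lateral_px_per_um = 3,
      z_step_um = 1 / 3, fragmentation_prob = 0, noise_sd = 0,
      cytoplasm_amplitude_rad = 0, seed = 21
    ))
  })
  recs <- build_records(e$labels, e$phase)
  expect_equal(nrow(recs), 12L)
  m <- merge(recs, e$truth, by = "id")
  expect_lt(max(abs(m$dmd_pg_per_um3.x / m$dmd_pg_per_um3.y - 1)), 0.05)
  # rho * V = M exactly for every record
  expect_equal(recs$dmd_pg_per_um3 * recs$volume_um3, recs$dry_mass_pg)
  # empty label volume -> empty table
  lv0 <- label_volume(array(0L, c(6, 6, 6)), 1, 1)
  pv0 <- phase_volume(array(0, c(6, 6, 6)), 1, 1)
  expect_equal(nrow(build_records(lv0, pv0)), 0L)
})

test_that("records with sphericity above 1 are excluded and counted", {
  # a well-resolved sphere keeps Sp <= 1; a tiny blob a few voxels across
  # has its surface underestimated and lands above 1, which the exclusion
  # rule treats as a segmentation artifact
  arr <- array(0L, c(48, 48, 48))
  ax <- 1:48
  arr[outer(outer((ax - 16)^2, (ax - 16)^2, "+"), (ax - 16)^2, "+") <= 8^2] <- 1L
  arr[outer(outer((ax - 38)^2, (ax - 38)^2, "+"), (ax - 38)^2, "+") <= 3^2] <- 2L
  lv <- label_volume(arr, 1, 1)
  pv <- phase_volume(array(0.1, dim(arr)), 1, 1)
  recs <- suppressMessages(build_records(lv, pv))
  expect_equal(recs$id, 1L)
  expect_identical(attr(recs, "n_dropped"), 1L)
  expect_true(all(recs$sphericity <= 1))
})

test_that("compartment assignment follows the normalized-radius threshold", {
  out <- assign_compartment(data.frame(
    cx_um = c(-10, 0, 10), cy_um = 0, cz_um = 0
  ))
  expect_equal(out$compartment, c("TE", "ICM", "TE"))
  expect_equal(out$normalized_radius, c(1, 0, 1))
  # symmetric cloud (centre at the origin, max distance 1):
  # radius 0.9 -> TE, 0.3 -> ICM, exactly 0.7 -> ICM (inclusive inside)
  ring <- data.frame(
    cx_um = c(1, -1, 0, 0, 0.9, -0.9, 0.3, -0.3, 0.7, -0.7),
    cy_um = c(0, 0, 1, -1, rep(0, 6)), cz_um = 0
  )
  ring <- assign_compartment(ring)
  expect_equal(ring$compartment[5:10], c("TE", "TE", "ICM", "ICM", "ICM", "ICM"))
  expect_equal(ring$normalized_radius[c(5, 7, 9)], c(0.9, 0.3, 0.7))
  # single nucleus: radius 0, ICM
  single <- assign_compartment(data.frame(cx_um = 3, cy_um = 4, cz_um = 5))
  expect_equal(single$normalized_radius, 0)
  expect_equal(single$compartment, "ICM")
})

test_that("dmd map is normalized, brighter on the denser shell, and flags empty input", {
  e <- small_blastocyst()
  recs <- data.frame(
    id = e$truth$id, dmd_pg_per_um3 = e$truth$dmd_pg_per_um3
  )
  mp <- dmd_map(e$labels, recs)
  expect_equal(max(mp), 1)
  expect_gte(min(mp), 0)
  te_vox <- unclass(e$labels) %in% e$truth$id[e$truth$compartment == "TE"]
  icm_vox <- unclass(e$labels) %in% e$truth$id[e$truth$compartment == "ICM"]
  expect_gt(mean(mp[te_vox]), mean(mp[icm_vox]))
  empty <- dmd_map(label_volume(array(0L, c(5, 5, 5)), 1, 1),
    data.frame(id = integer(0), dmd_pg_per_um3 = numeric(0)))
  expect_true(isTRUE(attr(empty, "empty")))
  expect_equal(max(empty), 0)
})
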