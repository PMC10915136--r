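lp <- link3d_params() # reference calibration: 50 px radius, 5 um gap

test_that("distant nuclei form separate trajectories, jittered ones stay linked", {
  # two nuclei 200 px apart over 10 slices
  slices <- lapply(1:10, function(z) {
    fake_slice(fake_objects(cx = c(100, 300), cy = c(100, 100)), c(400L, 400L))
  })
  trajs <- link_trajectories(slices, lp)
  expect_length(trajs, 2L)
  expect_true(all(vapply(trajs, nrow, integer(1)) == 10L))
  # +/- 10 px jitter keeps one trajectory
  set.seed(1)
  slices <- lapply(1:10, function(z) {
    fake_slice(fake_objects(100 + runif(1, -10, 10), 100 + runif(1, -10, 10)),
      c(256L, 256L)
    )
  })
  expect_length(link_trajectories(slices, lp), 1L)
})

test_that("gaps beyond 5 um start a new trajectory, shorter gaps bridge", {
  mk <- function(zs, nz) {
    lapply(seq_len(nz), function(z) {
      if (z %in% zs) {
        fake_slice(fake_objects(100, 100), c(256L, 256L))
      } else {
        fake_slice(fake_objects(numeric(0), numeric(0), numeric(0)), c(256L, 256L))
      }
    })
  }
  # present z = 1..5 and 12..16: 6 missing slices = 6 um gap -> 2 trajectories
  expect_length(link_trajectories(mk(c(1:5, 12:16), 16), lp), 2L)
  # 4 missing slices = 4 um gap -> bridged into 1 trajectory
  expect_length(link_trajectories(mk(c(1:5, 10:14), 14), lp), 1L)
})

test_that("stacked-sphere area profiles split; shallow or monotone ones do not", {
  mk_traj <- function(areas) {
    data.frame(
      z = seq_along(areas), label = 1L, cx = 100, cy = 100, area = areas
    )
  }
  two <- split_stacked(mk_traj(c(100, 400, 900, 400, 100, 400, 900, 400, 100)), lp)
  expect_length(two, 2L)
  expect_equal(vapply(two, nrow, integer(1)), c(4L, 5L))
  # monotone profile: no split
  expect_length(split_stacked(mk_traj(c(100, 300, 500, 700, 900, 1100)), lp), 1L)
  # shallow waist at 0.8 x peaks: below the 0.6 dip factor rule
  expect_length(
    split_stacked(mk_traj(c(100, 720, 900, 720, 900, 720, 100))), 1L
  )
})

test_that("3D filters remove small, thin and sparse objects and keep spheres", {
  dims <- c(160L, 160L)
  # 4000-voxel object: 20x20 square over 10 slices
  sq <- painted_stack(
    replicate(10, data.frame(cx = 80, cy = 80, r = 11.3), simplify = FALSE),
    dims
  )
  vol <- sum(vapply(sq, function(s) sum(s > 0), numeric(1)))
  expect_lt(vol, 5000)
  lv <- assemble_and_filter(link_trajectories(sq, lp), sq, lp)
  expect_equal(nrow(attr(lv, "objects")), 0L)
  # object spanning only 2 z planes (volume above the minimum)
  thin <- painted_stack(
    replicate(2, data.frame(cx = 80, cy = 80, r = 45), simplify = FALSE), dims
  )
  expect_gt(sum(vapply(thin, function(s) sum(s > 0), numeric(1))), 5000)
  lv <- assemble_and_filter(link_trajectories(thin, lp), thin, lp)
  expect_equal(nrow(attr(lv, "objects")), 0L)
  # digitized sphere radius 15 px, 30 slices deep: extent ~ pi/6, kept
  zr <- 15
  sph <- painted_stack(lapply(1:31, function(z) {
    rz2 <- 15^2 * (1 - ((z - 16) / zr)^2)
    if (rz2 <= 1) {
      data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
    } else {
      data.frame(cx = 80, cy = 80, r = sqrt(rz2))
    }
  }), dims)
  lv <- assemble_and_filter(link_trajectories(sph, lp), sph, lp)
  tab <- attr(lv, "objects")
  expect_equal(nrow(tab), 1L)
  expect_gt(tab$extent, 0.4)
  expect_lt(tab$extent, 0.6)
})

test_that("extent below 0.14 is filtered even when volume and depth pass", {
  # diagonally drifting disc: large bounding box, small occupied volume
  dims <- c(400L, 400L)
  diag <- painted_stack(lapply(1:10, function(z) {
    data.frame(cx = 30 + 30 * (z - 1), cy = 30 + 30 * (z - 1), r = 13)
  }), dims)
  vol <- sum(vapply(diag, function(s) sum(s > 0), numeric(1)))
  expect_gt(vol, 5000)
  trajs <- link_trajectories(diag, lp)
  expect_length(trajs, 1L) # 42 px steps are within the 50 px link radius
  lv <- assemble_and_filter(trajs, diag, lp)
  expect_equal(nrow(attr(lv, "objects")), 0L)
})

test_that("isotropic resampling preserves labels and integrates phase consistently", {
  e <- fixture("resample_embryo", function() {
    generate_embryo(synth_config("cleavage_sick",
      n_nuclei = 4, embryo_radius_um = 12, lateral_px_per_um = 3,
      z_step_um = 1, fragmentation_prob = 0, noise_sd = 0, seed = 8
    ))
  })
  iso <- resample_isotropic(e$labels, e$phase)
  f <- round(attr(e$labels, "dz_um") / attr(e$labels, "dx_um"))
  expect_equal(dim(iso$labels)[3], (dim(e$labels)[3] - 1L) * f + 1L)
  expect_setequal(unique(as.vector(unclass(iso$labels))), unique(as.vector(unclass(e$labels))))
  # total phase x voxel volume conserved within 1%
  tot_before <- sum(unclass(e$phase)) * attr(e$phase, "dx_um")^2 * attr(e$phase, "dz_um")
  tot_after <- sum(unclass(iso$phase)) * attr(iso$phase, "dx_um")^2 * attr(iso$phase, "dz_um")
  expect_lt(abs(tot_after / tot_before - 1), 0.01)
})

test_that("count map max equals the nucleus count and is zero when empty", {
  expect_equal(max(count_map(array(0L, c(5, 5, 4)))), 0L)
  arr <- array(0L, c(20, 20, 6))
  arr[2:4, 2:4, 1:2] <- 1L
  arr[10:12, 10:12, 2:4] <- 2L
  arr[16:18, 16:18, 4:6] <- 3L
  cm <- count_map(arr)
  expect_equal(max(cm), 3L)
})

test_that("filters applied in any order give the same surviving set", {
  set.seed(6)
  objs <- data.frame(
    vol = runif(50, 1000, 400000), depth = sample(1:40, 50, TRUE),
    extent = runif(50, 0.05, 0.8)
  )
  f_vol <- function(df) df[df$vol >= 5000 & df$vol <= 250000, ]
  f_dep <- function(df) df[df$depth >= 3, ]
  f_ext <- function(df) df[df$extent >= 0.14, ]
  a <- f_ext(f_dep(f_vol(objs)))
  b <- f_vol(f_ext(f_dep(objs)))
  c_ <- f_dep(f_vol(f_ext(objs)))
  expect_equal(a[order(as.numeric(rownames(a))), ], b[order(as.numeric(rownames(b))), ])
  expect_equal(a, c_[rownames(a), ])
})
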