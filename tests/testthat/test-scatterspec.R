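test_that("point model stamps one digital ball per centroid with union semantics", {
  one <- build_point_model(matrix(c(0, 0, 0), 1), extent_um = c(20, 20, 20),
    grid = 64L)
  expect_equal(sum(one), 7) # centre + 6 face neighbours
  expect_equal(attr(one, "n_points"), 1L)
  # well-separated centroids: 7 voxels each
  set.seed(2)
  cts <- as.matrix(expand.grid(x = c(-6, 0, 6), y = c(-6, 0, 6), z = 0))
  many <- build_point_model(cts, extent_um = c(20, 20, 20), grid = 64L)
  expect_equal(sum(many), 7 * nrow(cts))
  expect_equal(attr(many, "n_overlap"), 0L)
  # coincident centroids overlap and are logged
  dup <- build_point_model(rbind(c(0, 0, 0), c(0, 0, 0)),
    extent_um = c(20, 20, 20), grid = 64L
  )
  expect_equal(sum(dup), 7)
  expect_equal(attr(dup, "n_overlap"), 1L)
  expect_error(
    build_point_model(rbind(c(0, 0, 0), c(50, 0, 0)), extent_um = c(20, 20, 20)),
    "out of bounds"
  )
})

test_that("the power spectrum is invariant under translation of the arrangement", {
  cts <- rbind(c(-4, 2, 1), c(3, -3, 2), c(1, 4, -3))
  s1 <- compute_spectrum(build_point_model(cts,
    extent_um = c(40, 40, 40), grid = 64L
  ))
  s2 <- compute_spectrum(build_point_model(cts + 5,
    extent_um = c(40, 40, 40), grid = 64L
  ))
  expect_lt(max(abs(s1$power - s2$power)) / s1$peak_power, 1e-9)
})

test_that("DC power scales as N^2 for non-overlapping arrangements", {
  grid <- 64L
  ext <- c(30, 30, 30)
  single <- compute_spectrum(build_point_model(matrix(0, 1, 3), ext, grid))
  cts <- as.matrix(expand.grid(x = c(-8, 0, 8), y = c(-8, 8), z = c(-6, 6)))
  N <- nrow(cts)
  multi <- compute_spectrum(build_point_model(cts, ext, grid))
  expect_equal(multi$power[1], N^2 * single$power[1], tolerance = 1e-9)
  # Parseval: total power equals n_voxels x sum of squares of the field
  pm <- build_point_model(cts, ext, grid)
  P <- Mod(fft(unclass(pm)))^2
  expect_equal(sum(P), length(pm) * sum(unclass(pm)^2), tolerance = 1e-9)
})

test_that("half-power bandwidth handles exact, interpolated and absent crossings", {
  expect_equal(bandwidth_3db(list(k = 0:3, power = c(1, 0.8, 0.5, 0.2))), 2)
  k <- seq(0, 4, length.out = 401)
  bw <- bandwidth_3db(list(k = k, power = exp(-k^2)))
  expect_lt(abs(bw - sqrt(log(2))), diff(k)[1])
  nc <- bandwidth_3db(list(k = 0:2, power = c(1, 0.9, 0.8)))
  expect_equal(as.numeric(nc), 2)
  expect_true(isTRUE(attr(nc, "no_crossing")))
  expect_error(bandwidth_3db(list(k = 0:1, power = c(0, 0))), "positive peak")
})

test_that("compact arrangements have wider spectra than dispersed ones", {
  wider <- vapply(1:6, function(s) {
    set.seed(100 + s)
    dirs <- matrix(rnorm(25 * 3), 25, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2)) * runif(25)^(1 / 3)
    compact <- dirs * 12
    dispersed <- dirs * 24
    bwc <- scattering_bandwidth(compact, extent_um = c(60, 60, 60), grid = 64L)
    bwd <- scattering_bandwidth(dispersed, extent_um = c(60, 60, 60), grid = 64L)
    bwc$bw3dB > bwd$bw3dB
  }, logical(1))
  expect_gte(mean(wider), 5 / 6)
})

test_that("peak power does not decrease with the number of nuclei", {
  grid <- 64L
  ext <- c(40, 40, 40)
  set.seed(5)
  pts <- as.matrix(expand.grid(x = c(-12, -4, 4, 12), y = c(-12, -4, 4, 12), z = c(-8, 0, 8)))
  peaks <- vapply(c(4, 12, 24, 48), function(n) {
    compute_spectrum(build_point_model(pts[seq_len(n), , drop = FALSE], ext, grid))$peak_power
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})
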