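test_that("PSNR follows the closed form", {
  y <- matrix(runif(64 * 64), 64, 64)
  expect_equal(psnr(y, y), Inf)
  expect_equal(psnr(y, y + 0.1, data_range = 1), 20) # MSE 0.01
  # doubling the error amplitude lowers PSNR by 20 log10(2) ~ 6.02 dB
  e <- matrix(rnorm(64 * 64, 0, 0.05), 64, 64)
  expect_equal(psnr(y, y + e) - psnr(y, y + 2 * e), 20 * log10(2))
  expect_error(psnr(y, matrix(0, 2, 2)), "shape")
})

test_that("identical images give MS-SSIM 1 and anti-correlated patterns go negative", {
  set.seed(1)
  y <- matrix(runif(192 * 192), 192, 192)
  expect_equal(ms_ssim(y, y), 1)
  # checkerboard: local Gaussian means vanish, so the luminance term is ~1
  # while the structure term of the negated image is ~ -1
  z <- 0.5 * outer((-1)^(1:192), (-1)^(1:192))
  v <- ms_ssim(z, -z, metric_config(scales = 1, weights = 1, data_range = 1))
  expect_lt(v, 0)
})

test_that("single-scale MS-SSIM matches a brute-force structural-similarity oracle", {
  set.seed(7)
  y <- matrix(runif(96 * 96), 96, 96)
  yh <- y + matrix(rnorm(96 * 96, 0, 0.08), 96, 96)
  cfg <- metric_config(scales = 1, weights = 1, data_range = 1)
  got <- ms_ssim(y, yh, cfg)
  # oracle: direct windowed computation with an explicit Gaussian kernel
  r <- 5
  k1 <- exp(-((-r:r)^2) / (2 * 1.5^2))
  K <- outer(k1, k1)
  K <- K / sum(K)
  C1 <- 0.01^2
  C2 <- 0.03^2
  idx <- pmin(pmax((1:(96 + 2 * r)) - r, 1), 96) # replicate padding
  Y <- y[idx, idx]
  Yh <- yh[idx, idx]
  vals_l <- vals_cs <- matrix(NA_real_, 96, 96)
  for (i in 1:96) {
    for (j in 1:96) {
      wy <- Y[i:(i + 2 * r), j:(j + 2 * r)]
      wyh <- Yh[i:(i + 2 * r), j:(j + 2 * r)]
      m1 <- sum(K * wy)
      m2 <- sum(K * wyh)
      s11 <- sum(K * wy^2) - m1^2
      s22 <- sum(K * wyh^2) - m2^2
      s12 <- sum(K * wy * wyh) - m1 * m2
      vals_l[i, j] <- (2 * m1 * m2 + C1) / (m1^2 + m2^2 + C1)
      vals_cs[i, j] <- (2 * s12 + C2) / (s11 + s22 + C2)
    }
  }
  oracle <- mean(vals_l) * mean(vals_cs)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("Pearson loss follows the correlation identities", {
  set.seed(3)
  y <- matrix(runif(50 * 50), 50, 50)
  expect_equal(pearson_loss(y, 2 * y + 3), 0)
  expect_equal(pearson_loss(y, -y), 4)
  yh <- matrix(runif(50 * 50), 50, 50)
  r <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(pearson_loss(y, yh), (1 - r)^2, tolerance = 1e-12)
  expect_error(pearson_loss(y, matrix(1, 50, 50)), "constant")
})

test_that("the combination loss applies the (2, 1, 0.5) weights and vanishes at equality", {
  set.seed(9)
  y <- matrix(runif(192 * 192), 192, 192)
  expect_equal(combo_loss(y, y), 0)
  yh <- y * 0.9 + matrix(rnorm(192 * 192, 0, 0.05), 192, 192)
  cfg <- metric_config(scales = 2, weights = c(0.5, 0.5), data_range = 1)
  expect_equal(
    combo_loss(y, yh, cfg),
    2 * mean(abs(y - yh)) + (1 - ms_ssim(y, yh, cfg)) + 0.5 * pearson_loss(y, yh)
  )
  # weights (1, 0, 0) reduce to the L1 loss exactly
  cfg_l1 <- metric_config(loss_weights = c(1, 0, 0))
  expect_equal(combo_loss(y, yh, cfg_l1), mean(abs(y - yh)))
  expect_gt(combo_loss(y, yh, cfg), 0)
})

test_that("metrics are symmetric in their arguments", {
  set.seed(12)
  y <- matrix(runif(192 * 192), 192, 192)
  yh <- matrix(runif(192 * 192), 192, 192)
  expect_equal(psnr(y, yh), psnr(yh, y))
  expect_equal(ms_ssim(y, yh), ms_ssim(yh, y))
  expect_equal(pearson_loss(y, yh), pearson_loss(yh, y))
})

test_that("images too small for the scale count reduce scales with a warning", {
  y <- matrix(runif(40 * 40), 40, 40)
  expect_warning(v <- ms_ssim(y, y), "scales")
  expect_equal(v, 1)
})
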