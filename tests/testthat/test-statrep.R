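test_that("the normality gate is calibrated on normal samples and rejects exponential ones", {
  set.seed(31)
  pass <- vapply(1:200, function(i) {
    normality_gate(rnorm(500), rep("a", 500))$normal
  }, logical(1))
  expect_gt(mean(pass), 0.90)
  expect_lt(mean(pass), 0.985)
  rej <- vapply(1:100, function(i) {
    !normality_gate(rexp(500), rep("a", 500))$normal
  }, logical(1))
  expect_gte(mean(rej), 0.99)
  # constant and tiny samples are degenerate, treated as non-normal
  g <- normality_gate(c(rep(1, 10), rnorm(10)), rep(c("a", "b"), each = 10))
  expect_false(g$normal)
  expect_true(g$degenerate[["a"]])
})

test_that("identical groups are not flagged by either branch", {
  set.seed(5)
  v <- rep(rnorm(40), 3)
  g <- rep(c("H", "I", "S"), each = 40)
  cmp <- compare_groups(v, g, alpha_nonparam = 0.05, alpha_param = 0.05)
  expect_gt(cmp$omnibus_p, 0.5)
  expect_false(any(cmp$pairwise$significant))
})

test_that("the rank branch flags exactly the shifted pairs (frozen Dunn oracle)", {
  v <- c(1:5, 6:10, 6:10)
  g <- rep(c("g1", "g2", "g3"), each = 5)
  # alpha_normality = 1 forces the non-parametric branch regardless of the
  # (underpowered at n = 5) per-group normality verdicts
  cmp <- compare_groups(v, g, alpha_nonparam = 0.05, alpha_normality = 1)
  expect_equal(cmp$branch, "KW+Dunn-Holm")
  pw <- cmp$pairwise
  key <- paste(pw$group1, pw$group2)
  # hand-computed: mean ranks 3, 10.5, 10.5; tie term 30/(12*14);
  # z12 = -7.5 / sqrt((20 - 30/168) * 0.4) = -2.6636, Holm x3
  expect_equal(pw$statistic[key == "g1 g2"], -2.663566, tolerance = 1e-6)
  expect_equal(pw$p_adj[key == "g1 g2"], 3 * 2 * pnorm(-2.663566), tolerance = 1e-4)
  expect_equal(pw$significant, c(TRUE, TRUE, FALSE))
})

test_that("Holm-adjusted p-values are monotone in the raw order and >= raw", {
  set.seed(9)
  v <- c(rnorm(30), rnorm(30, 0.5), rnorm(30, 2))
  cmp <- compare_groups(v, rep(c("a", "b", "c"), each = 30))
  pw <- cmp$pairwise[order(cmp$pairwise$p_raw), ]
  expect_true(all(diff(pw$p_adj) >= -1e-12))
  expect_true(all(pw$p_adj >= pw$p_raw))
})

test_that("normally distributed features take the ANOVA branch with Levene reported", {
  set.seed(17)
  v <- c(rnorm(200, 10), rnorm(200, 10.5), rnorm(200, 12))
  g <- rep(c("H", "I", "S"), each = 200)
  cmp <- compare_groups(v, g)
  expect_equal(cmp$branch, "ANOVA+t-Holm")
  expect_false(is.na(cmp$levene_p))
  expect_true(cmp$significant) # 1.5 sd shift at n = 200 is overwhelming
  expect_error(compare_groups(numeric(0), character(0)), "two non-empty")
})

test_that("TE/ICM density contrast is detected and the null is not", {
  recs <- data.frame(
    compartment = rep(c("TE", "ICM"), each = 350),
    dmd_pg_per_um3 = c(rnorm(350, 0.075, 0.01), rnorm(350, 0.0625, 0.01))
  )
  set.seed(3)
  out <- te_icm_test(recs)
  expect_true(out$significant)
  null <- recs
  set.seed(4)
  null$dmd_pg_per_um3 <- rnorm(700, 0.07, 0.01)
  expect_false(te_icm_test(null)$significant)
  ident <- data.frame(
    compartment = rep(c("TE", "ICM"), each = 20),
    dmd_pg_per_um3 = rep(1:20, 2)
  )
  expect_gt(te_icm_test(ident)$omnibus_p, 0.9)
  one_sided <- data.frame(compartment = rep("TE", 5), dmd_pg_per_um3 = 1:5)
  expect_false(te_icm_test(one_sided)$testable)
})

test_that("stats_report assembles one row per feature", {
  set.seed(8)
  d <- data.frame(
    a = c(rnorm(60), rnorm(60, 3)), b = rexp(120),
    health = rep(c("HI", "S"), each = 60)
  )
  rep_ <- stats_report(d, group_col = "health")
  expect_equal(rep_$table$feature, c("a", "b"))
  expect_equal(nrow(rep_$table), 2L)
})
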