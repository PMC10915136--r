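test_that("training separates a linearly separable synthetic feature set", {
  tab <- toy_feature_table(2000, seed = 1)
  tr_idx <- fixture("fbm_split", function() {
    set.seed(2)
    sample(nrow(tab), 3000)
  })
  model <- fixture("fbm_model", function() {
    train_fbm(tab[tr_idx, ], tab$health[tr_idx], seed = 7)
  })
  held <- setdiff(seq_len(nrow(tab)), tr_idx)
  pred <- predict_items(model, tab[held, ])
  expect_gte(mean(pred$class == tab$health[held]), 0.95)
  # a row at the sick-class centroid is graded S with score > 0.5
  s_centroid <- as.data.frame(lapply(
    tab[tab$health == "S", names(tab) != "health"], mean
  ))
  ps <- predict_items(model, s_centroid)
  expect_equal(ps$class, "S")
  expect_gt(ps$score, 0.5)
  # batch order is preserved
  p2 <- predict_items(model, tab[held[1:20], ])
  expect_equal(p2, predict_items(model, tab[held, ])[1:20, ], ignore_attr = TRUE)
})

test_that("training is deterministic and the L2 penalty shrinks the weights", {
  tab <- toy_feature_table(150, seed = 3)
  m1 <- train_fbm(tab, tab$health, seed = 5, max_evals = 40)
  m2 <- train_fbm(tab, tab$health, seed = 5, max_evals = 40)
  expect_identical(m1$wb, m2$wb)
  m_big <- train_fbm(tab, tab$health, seed = 5, max_evals = 40, lambda = 10)
  norm <- function(m) sum(vapply(m$wb$W, function(w) sum(w^2), numeric(1)))
  expect_lt(norm(m_big), norm(m1))
  expect_error(train_fbm(tab, rep("S", nrow(tab))), "single class")
  tab$bw3dB[1] <- NA
  expect_error(train_fbm(tab, tab$health), "missing")
})

test_that("an all-zero network predicts the tie class HI with probability 0.5", {
  zero <- structure(
    list(
      wb = list(
        W = list(matrix(0, 5, 10), matrix(0, 10, 2), matrix(0, 2, 2)),
        b = list(rep(0, 10), rep(0, 2), rep(0, 2))
      ),
      sizes = c(5L, 10L, 2L, 2L),
      features = c("bw3dB", "nuc_count", "dmd_pg_per_um3", "surface_um2", "sphericity"),
      classes = c("HI", "S"), center = rep(0, 5), scale = rep(1, 5)
    ),
    class = "fbm_model"
  )
  p <- predict_items(zero, toy_feature_table(3, seed = 1))
  expect_true(all(p$class == "HI"))
  expect_equal(p$score, rep(0.5, 6))
  expect_error(predict_items(zero, data.frame(bw3dB = 1)), "missing feature")
})

test_that("max voting aggregates votes, confidences and ties as specified", {
  v <- data.frame(class = c("HI", "HI", "S"), score = c(0.9, 0.8, 0.7))
  g <- max_vote(v)
  expect_equal(g$class, "HI")
  expect_equal(g$cp, 0.85)
  expect_equal(g$majority_fraction, 2 / 3)
  expect_false(g$tie)
  all_s <- data.frame(class = rep("S", 4), score = c(0.6, 0.7, 0.8, 0.9))
  expect_equal(max_vote(all_s)$cp, 0.75)
  tied <- data.frame(class = c("HI", "HI", "S", "S"), score = rep(0.9, 4))
  gt <- max_vote(tied)
  expect_equal(gt$class, "S")
  expect_true(gt$tie)
  expect_error(max_vote(v[0, ]), "empty")
})

test_that("grades are invariant to item order and cp bounded by majority scores", {
  set.seed(8)
  v <- data.frame(
    class = sample(c("HI", "S"), 31, TRUE, prob = c(0.7, 0.3)),
    score = runif(31, 0.5, 1)
  )
  g <- max_vote(v)
  for (i in 1:5) {
    gp <- max_vote(v[sample(nrow(v)), ])
    expect_equal(gp$class, g$class)
    expect_equal(gp$cp, g$cp)
    expect_equal(gp$majority_fraction, g$majority_fraction)
  }
  maj <- v$score[v$class == g$class]
  expect_gte(g$cp, min(maj))
  expect_lte(g$cp, max(maj))
})

test_that("sparse voting enforces the spacing and slice-count policy", {
  set.seed(4)
  preds <- data.frame(
    class = c(rep("HI", 80), rep("S", 20)), score = runif(100, 0.6, 1),
    z_um = 0:99
  )
  g <- sparse_vote(preds, step_um = 10)
  expect_equal(length(attr(g, "selected")), 10L)
  expect_equal(g$class, "HI")
  expect_error(sparse_vote(preds, step_um = 15), "exceeds the 10")
  six <- preds[1:6, ]
  expect_error(sparse_vote(six, step_um = 1), "minimum is 7")
  # force overrides both policies
  expect_s3_class(sparse_vote(six, step_um = 15, force = TRUE), "grade_result")
})

test_that("model serialization round-trips through JSON", {
  tab <- toy_feature_table(100, seed = 6)
  m <- train_fbm(tab, tab$health, seed = 2, max_evals = 20)
  path <- tempfile(fileext = ".json")
  write_fbm(m, path)
  m2 <- read_fbm(path)
  p1 <- predict_items(m, tab)
  p2 <- predict_items(m2, tab)
  expect_equal(p1, p2)
})
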