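test_that("random-forest config carries the baseline settings", {
  cfg <- rf_config("classification")
  expect_equal(cfg$n_trees, 100L)
  expect_equal(cfg$max_depth, 10L)
  expect_error(rf_config(n_trees = 0), "n_trees")
})

test_that("flattening windows produces 120- and 2520-dim vectors", {
  ws12 <- toy_windows(c(0L, 1L), n_features = 12L)
  expect_equal(dim(flatten_windows(ws12)), c(2L, 120L))
  ws252 <- toy_windows(c(0L, 1L), n_features = 252L)
  expect_equal(ncol(flatten_windows(ws252)), 2520L)
})

test_that("a regression forest on a constant target predicts that constant", {
  codes <- rep(2L, 30) # all moderate heat phasic -> value 2/3
  ws <- encode_labels(filter_windows(toy_windows(codes, seed = 3), "HPD"))
  fit <- train_rf(ws, rf_config("regression"))
  pred <- predict_windows(fit, ws)
  expect_true(all(abs(pred$values - 2 / 3) < 1e-9))
})

test_that("a separable two-class problem is fit almost perfectly", {
  codes <- rep(c(0L, 3L), each = 40)
  ws <- encode_labels(filter_windows(
    toy_windows(codes, informative = TRUE, seed = 4), "HPD"))
  fit <- train_rf(ws, rf_config("classification", seed = 2))
  acc <- mean(predicted_class(predict_windows(fit, ws)) == ws$class_index)
  expect_gte(acc, 0.99)
})

test_that("single-class classification training is rejected", {
  ws <- encode_labels(filter_windows(toy_windows(rep(1L, 10)), "HPD"))
  expect_error(train_rf(ws, rf_config("classification")), "single class")
})

test_that("forest predictions are reproducible given the seed", {
  codes <- rep(c(0L, 1L, 2L), each = 15)
  ws <- encode_labels(filter_windows(toy_windows(codes, seed = 5), "HPD"))
  p1 <- predict_windows(train_rf(ws, rf_config("classification", seed = 9)), ws)
  p2 <- predict_windows(train_rf(ws, rf_config("classification", seed = 9)), ws)
  expect_identical(p1$scores, p2$scores)
})

test_that("classification scores are normalized and regression stays in [0,1]", {
  codes <- rep(c(0L, 1L, 3L), each = 12)
  ws <- encode_labels(filter_windows(toy_windows(codes, seed = 6), "HPD"))
  pc <- predict_windows(train_rf(ws, rf_config("classification")), ws)
  expect_true(all(pc$scores >= 0))
  expect_equal(rowSums(pc$scores), rep(1, n_windows(ws)))
  pr <- predict_windows(train_rf(ws, rf_config("regression")), ws)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  # empty prediction request
  empty <- subset_windows(ws, integer(0))
  expect_equal(n_predictions(predict_windows(train_rf(ws, rf_config("regression")),
                                             empty)), 0L)
})

test_that("the trivial predictor always votes no pain", {
  triv <- trivial_predictor(5, "classification",
                            classes = dataset_classes("HPD"))
  expect_true(all(predicted_class(triv) == 0L))
  expect_true(all(triv$scores[, "BL"] == 1))
  reg <- trivial_predictor(4, "regression")
  expect_true(all(reg$values == 0))
  expect_equal(n_predictions(trivial_predictor(0, "regression")), 0L)
})

test_that("sample weighting duplicates exactly the confidently scored windows", {
  codes <- rep(c(0L, 1L, 2L, 3L), each = 12)
  fad <- encode_labels(filter_windows(
    toy_windows(codes, n_features = 6L, informative = TRUE, seed = 7), "HPD"))
  cfg <- rf_config("classification", seed = 3)
  idx <- sample_weighting(fad, threshold = 0.3, cfg = cfg)
  k <- attr(idx, "n_duplicated")
  n <- n_windows(fad)
  expect_equal(length(idx), n + k)
  expect_identical(idx[seq_len(n)], seq_len(n)) # stable ordering
  # independent count of qualifying windows
  scores <- predict_windows(train_rf(fad, cfg), fad)$scores
  true_s <- scores[cbind(seq_len(n), fad$class_index + 1L)]
  expect_equal(k, sum(true_s > 0.3))
  expect_gte(k, 1L)
  # augmentation only ever adds windows
  aug <- augment_windows(fad, idx)
  expect_equal(n_windows(aug), n + k)
  expect_identical(aug$code[seq_len(n)], fad$code)
  # an unreachable threshold leaves the set untouched
  ident <- sample_weighting(fad, threshold = 1, cfg = cfg)
  expect_identical(as.integer(ident), seq_len(n))
})
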