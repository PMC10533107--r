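test_that("architecture table matches the six reference configurations", {
  a <- recurrent_arch("A(c)")
  expect_equal(c(a$units, a$dense_units, a$output_units), c(4L, 128L, 7L))
  b <- recurrent_arch("B(c)")
  expect_equal(c(b$units, b$dense_units, b$output_units), c(8L, 64L, 7L))
  cc <- recurrent_arch("C(c)")
  expect_equal(c(cc$units, cc$dense_units, cc$output_units), c(4L, 128L, 4L))
  d <- recurrent_arch("D(c)")
  expect_equal(c(d$units, d$dense_units, d$output_units), c(8L, 64L, 4L))
  for (id in c("A(r)", "C(r)")) {
    r <- recurrent_arch(id)
    expect_equal(c(r$units, r$dense_units, r$output_units), c(4L, 128L, 1L))
    expect_equal(r$output_activation, "sigmoid")
    expect_equal(r$loss, "bce")
  }
  expect_equal(recurrent_arch("B(r)")$units, 8L)
  expect_equal(recurrent_arch("A(c)")$loss, "cce")
  expect_error(recurrent_arch("E(c)"), "unknown architecture")
  # default mapping: 7-class -> A-shaped, 4-class -> C-shaped
  expect_equal(default_arch("PD", "classification")$id, "A(c)")
  expect_equal(default_arch("HPD", "regression")$id, "C(r)")
})

test_that("analytic LSTM gradients match central finite differences", {
  pm <- asNamespace("painmonitor")
  for (act in c("relu", "tanh")) {
    set.seed(42)
    arch <- recurrent_arch("C(c)")
    d <- 5L; n <- 6L
    X <- array(rnorm(n * 10 * d), c(n, 10, d))
    Y <- diag(4)[sample(1:4, n, replace = TRUE), ]
    params <- pm$lstm_init(d, arch)
    fwd <- pm$lstm_forward(params, X, arch, act, keep_cache = TRUE)
    gr <- pm$lstm_backward(params, X, Y, arch, fwd, act)
    eps <- 1e-6
    worst <- 0
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(8, length(params[[nm]])))) {
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        num <- (pm$lstm_loss(pm$lstm_forward(up, X, arch, act)$out, Y, arch) -
                  pm$lstm_loss(pm$lstm_forward(dn, X, arch, act)$out, Y, arch)) /
          (2 * eps)
        worst <- max(worst, abs(num - gr[[nm]][i]) / max(1e-4, abs(num)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("trained classifier outputs normalized scores of the right width", {
  codes <- rep(c(0L, 1L, 2L, 3L), each = 10)
  ws <- encode_labels(filter_windows(
    toy_windows(codes, n_features = 3L, informative = TRUE, seed = 1), "HPD"))
  fit <- train_recurrent(ws, recurrent_arch("C(c)"), lr = 1e-2, epochs = 20,
                         batch_size = 16, seed = 1)
  pred <- predict_windows(fit, ws)
  expect_equal(ncol(pred$scores), 4L)
  expect_equal(rowSums(pred$scores), rep(1, n_windows(ws)), tolerance = 1e-9)
  expect_true(all(pred$scores >= 0))
})

test_that("trained regressor stays in [0,1] and learns a separable signal", {
  codes <- rep(c(0L, 3L), each = 30)
  ws <- encode_labels(filter_windows(
    toy_windows(codes, n_features = 3L, informative = TRUE, seed = 2), "HPD"))
  fit <- train_recurrent(ws, recurrent_arch("C(r)"), lr = 1e-2, epochs = 40,
                         batch_size = 16, seed = 1)
  pred <- predict_windows(fit, ws)
  expect_true(all(pred$values >= 0 & pred$values <= 1))
  # the two classes separate: predictions correlate with the target
  expect_gt(cor(pred$values, ws$value), 0.9)
})

test_that("recurrent training is reproducible and validates shapes", {
  codes <- rep(c(0L, 1L), each = 10)
  ws <- encode_labels(filter_windows(
    toy_windows(codes, n_features = 3L, seed = 3), "HPD"))
  f1 <- train_recurrent(ws, recurrent_arch("C(r)"), lr = 1e-3, epochs = 3,
                        batch_size = 8, seed = 7)
  f2 <- train_recurrent(ws, recurrent_arch("C(r)"), lr = 1e-3, epochs = 3,
                        batch_size = 8, seed = 7)
  expect_identical(f1$params, f2$params)
  other <- toy_windows(codes, n_features = 5L, seed = 3)
  expect_error(predict_windows(f1, other), "dimensionality")
  # class-count mismatch between head and dataset
  expect_error(train_recurrent(ws, recurrent_arch("A(c)")), "class count")
})
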