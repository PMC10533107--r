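test_that("finite differences match hand-computed values", {
  d <- finite_derivatives(c(1, 2, 4, 7))
  expect_equal(d$d1, c(1, 2, 3))
  expect_equal(d$d2, c(1, 1))
  const <- finite_derivatives(rep(3, 10))
  expect_true(all(const$d1 == 0) && all(const$d2 == 0))
  ramp <- finite_derivatives(0.5 * (0:9))
  expect_equal(unique(ramp$d1), 0.5)
  expect_true(all(ramp$d2 == 0))
  expect_error(finite_derivatives(c(1, 2)), "3 samples")
})

test_that("series summary returns (min, max, mean, population std)", {
  expect_equal(unname(summarize_series(rep(2.5, 6))), c(2.5, 2.5, 2.5, 0))
  s <- summarize_series(c(1, 2, 4))
  expect_equal(unname(s), c(1, 4, 7 / 3, sqrt(14) / 3))
  x <- rnorm(50)
  expect_equal(summarize_series(x), summarize_series(sample(x)))
  expect_error(summarize_series(numeric(0)), "empty")
})

test_that("descriptor frames have 12 features per channel", {
  set.seed(1)
  eda <- matrix(rnorm(25 * 20), ncol = 1)
  f_eda <- compute_descriptor_frames(eda)
  expect_equal(dim(f_eda), c(20L, 12L))
  facial <- matrix(rnorm(25 * 20 * 21), ncol = 21)
  f_fad <- compute_descriptor_frames(facial)
  expect_equal(dim(f_fad), c(20L, 252L))
})

test_that("constant input collapses every frame to (c,c,c,0) and zero derivatives", {
  frames <- compute_descriptor_frames(matrix(4.2, 25 * 5, 1))
  expect_true(all(frames[, 1:3] == 4.2))
  expect_true(all(frames[, 4:12] == 0))
})

test_that("descriptor frames match the brute-force oracle on random 60-s inputs", {
  for (seed in 1:3) {
    set.seed(seed)
    ch <- matrix(rnorm(60 * 25 * 3), ncol = 3)
    fast <- compute_descriptor_frames(ch)
    slow <- brute_force_frames(ch)
    expect_lt(max(abs(unname(fast) - slow)), 1e-10)
  }
})

test_that("person standardization zeroes means, scales variance and guards degeneracy", {
  set.seed(2)
  frames <- matrix(rnorm(200, mean = 5, sd = 3), 20, 10)
  frames[, 4] <- 7 # zero-variance feature
  z <- person_standardize(frames, "S1")
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z[, -4], 2, sd)), rep(1, 9))
  expect_true(all(z[, 4] == 0))
  expect_error(person_standardize(frames[1, , drop = FALSE], "S1"),
               "at least 2 frames")
})

test_that("standardizing one subject is unaffected by other subjects", {
  set.seed(3)
  fa <- matrix(rnorm(100), 10, 10)
  fb <- matrix(rnorm(50, 10, 5), 5, 10)
  alone <- person_standardize(fa, "A")
  joint <- person_standardize(rbind(fa, fb), rep(c("A", "B"), c(10, 5)))
  expect_equal(joint[1:10, ], alone)
})

test_that("label shifting delays pain onsets and leaves all-baseline streams alone", {
  labels <- rep(0L, 25 * 20)
  labels[(10 * 25 + 1):(15 * 25)] <- 3L # pain from t = 10 s to 15 s
  shifted <- shift_labels(labels, 3)
  expect_equal(which(shifted == 3L)[1] - 1L, 13L * 25L)
  expect_identical(shift_labels(labels, 0), labels)
  bl <- rep(0L, 100)
  expect_identical(shift_labels(bl, 3), bl)
})

test_that("per-second labels use the majority with intensity and artifact tie-breaks", {
  second <- c(rep(0L, 12), rep(3L, 13)) # 13/25 pain -> majority pain
  expect_equal(second_labels(second), 3L)
  tie <- c(rep(1L, 12), rep(3L, 12), 0L) # intensity 3 beats intensity 1
  expect_equal(second_labels(tie), 3L)
  art <- c(rep(-10L, 12), rep(3L, 12), 0L) # artifact wins ties
  expect_equal(second_labels(art), -10L)
})

test_that("window count is T - 10 and shapes follow the modality", {
  set.seed(4)
  frames <- matrix(rnorm(30 * 12), 30, 12)
  ws <- build_windows(frames, rep(0L, 30))
  expect_equal(n_windows(ws), 20L)
  expect_equal(dim(ws$x)[2:3], c(10L, 12L))
  expect_equal(range(ws$t_end), c(10L, 29L))
  # exactly 10 s -> zero windows; below 10 s -> error
  empty <- build_windows(frames[1:10, ], rep(0L, 10))
  expect_equal(n_windows(empty), 0L)
  expect_error(build_windows(frames[1:9, ], rep(0L, 9)), "cannot form")
})

test_that("windows carry the shifted label of their end second", {
  frames <- matrix(seq_len(40 * 2), 40, 2)
  sec <- rep(0L, 40); sec[21:25] <- 5L # pain at seconds 20-24 (0-based)
  ws <- build_windows(frames, sec)
  expect_equal(ws$code[ws$t_end %in% 20:24], rep(5L, 5))
  # feature rows are the 10 frames before the label second
  w <- ws$x[which(ws$t_end == 20L), , ]
  expect_equal(w[, 1], frames[11:20, 1])
})

test_that("session windows are deterministic and shaped by modality", {
  cfg <- tiny_config(seed = 6L)
  co <- generate_cohort(cfg)
  s <- co$sessions[[1]]
  a <- session_windows(s, "eda")
  b <- session_windows(s, "eda")
  expect_identical(a$x, b$x)
  expect_equal(dim(a$x)[2:3], c(10L, 12L))
  expect_equal(dim(session_windows(s, "facial")$x)[3], 252L)
  expect_equal(n_windows(a),
               floor(length(s$labels) / 25) - 10L)
})
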