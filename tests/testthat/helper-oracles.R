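# Independent oracles and tiny fixtures shared across tests.

# Brute-force per-second descriptor frames: direct loops over seconds,
# channels and derivative orders, kept deliberately naive and independent of
# the vectorized implementation.
brute_force_frames <- function(channels, rate = 25) {
  if (is.null(dim(channels))) channels <- matrix(channels, ncol = 1)
  n_sec <- floor(nrow(channels) / rate)
  out <- NULL
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (s in seq_len(n_sec) - 1L) {
    row <- c()
    for (ch in seq_len(ncol(channels))) {
      x <- channels[, ch]
      d1 <- x[-1] - x[-length(x)]
      d2 <- d1[-1] - d1[-length(d1)]
      for (series in list(x, d1, d2)) {
        lo <- s * rate + 1L
        hi <- min(s * rate + rate, length(series))
        seg <- series[lo:hi]
        row <- c(row, min(seg), max(seg), mean(seg), pop_sd(seg))
      }
    }
    out <- rbind(out, row)
  }
  unname(out)
}

# Two-way ANOVA oracle for ICC(3,1) with k = 2 raters, via lm/anova.
icc_oracle <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y), row = factor(rep(seq_len(n), 2)),
                   col = factor(rep(1:2, each = n)))
  a <- stats::anova(stats::lm(v ~ row + col, data = df))
  msr <- a["row", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse)
}

# A window_set with prescribed label codes and random (seeded) features;
# features are mildly class-informative when `informative` is TRUE.
toy_windows <- function(codes, subject = "S1", n_features = 2L,
                        informative = FALSE, seed = 1) {
  set.seed(seed)
  n <- length(codes)
  x <- array(rnorm(n * 10 * n_features), c(n, 10, n_features))
  if (informative) {
    info <- decode_label(codes)
    x <- x + array(rep(info$intensity, 10 * n_features), c(n, 10, n_features))
  }
  window_set(x, codes, rep(subject, n), seq_along(codes) + 9L)
}

# Small generator configuration used where the full protocol is overkill.
tiny_config <- function(n_subjects = 3L, seed = 1L, ...) {
  generator_config(n_subjects = n_subjects, phasic_reps = 2L,
                   tonic_pause_s = 30, artifact_fraction = 0,
                   seed = seed, ...)
}
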