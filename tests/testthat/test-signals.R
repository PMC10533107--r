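test_that("zero gain, zero drift and zero noise give a constant baseline", {
  set.seed(1)
  cfg <- tiny_config()
  sch <- generate_schedule(cfg)
  prof <- subject_profile("S1", eda_gain = 0, noise_sd = 0,
                          drift_amp = 0, amp_jitter = 0)
  eda <- synthesize_eda(sch, prof, cfg)
  expect_equal(diff(range(eda)), 0)
  expect_equal(eda[1], prof$baseline_eda)
})

test_that("a single noiseless SCR peaks at onset + latency + kernel peak offset", {
  set.seed(1)
  cfg <- generator_config(phasic_reps = 1L, tonic_reps = 0L,
                          qualities = "heat", intensities = 2L,
                          artifact_fraction = 0)
  sch <- generate_schedule(cfg)
  prof <- subject_profile("S1", scr_latency_s = 2, noise_sd = 0,
                          drift_amp = 0, amp_jitter = 0)
  eda <- synthesize_eda(sch, prof, cfg)
  peak_t <- (which.max(eda) - 1) / 25
  expected <- sch$onset_s[1] + 2 + scr_kernel_peak_time(prof$scr_rise_s,
                                                        prof$scr_decay_s)
  expect_lt(abs(peak_t - expected), 0.05) # one-sample discretization
  # peak amplitude = gain * intensity above baseline
  expect_equal(max(eda) - prof$baseline_eda, prof$eda_gain * 2,
               tolerance = 1e-3)
})

test_that("mean SCR peak amplitude increases strictly with intensity", {
  set.seed(7)
  cfg <- generator_config(n_subjects = 1L, tonic_reps = 0L,
                          artifact_fraction = 0)
  sch <- generate_schedule(cfg)
  prof <- subject_profile("S1", noise_sd = 0, drift_amp = 0)
  eda <- synthesize_eda(sch, prof, cfg)
  peak_amp <- function(intensity) {
    ev <- sch[sch$intensity == intensity & sch$stim_type == "phasic", ]
    mean(vapply(seq_len(nrow(ev)), function(k) {
      i0 <- round((ev$onset_s[k] + 1) * 25); i1 <- i0 + 7 * 25
      max(eda[i0:i1]) - prof$baseline_eda
    }, numeric(1)))
  }
  amps <- vapply(1:3, peak_amp, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("facial output has 21 channels and responds per expressiveness", {
  set.seed(5)
  cfg <- tiny_config()
  sch <- generate_schedule(cfg)
  cat1 <- subject_profile("S1", expressiveness_category = 1L,
                          facial_gain = 0, noise_sd = 0)
  flat <- synthesize_facial(sch, cat1, cfg)
  expect_equal(ncol(flat), 21L)
  expect_true(all(apply(flat[, facial_responsive_channels()], 2,
                        function(v) diff(range(v))) == 0))
  # mean bump amplitude is monotone in the expressiveness category
  bump <- vapply(1:4, function(cat) {
    set.seed(10 + cat)
    prof <- subject_profile("S1", expressiveness_category = cat,
                            facial_gain = 0.4 * (cat - 1),
                            noise_sd = 0, amp_jitter = 0)
    f <- synthesize_facial(sch, prof, cfg)
    max(f[, facial_responsive_channels()[1]])
  }, numeric(1))
  expect_true(all(diff(bump) >= 0))
  expect_equal(bump[1], 0)
})

test_that("artifact injection hits the target fraction without touching signals", {
  set.seed(9)
  cfg <- generator_config(n_subjects = 1L, phasic_reps = 5L,
                          artifact_fraction = 0.05)
  prof <- subject_profile("S1")
  sess <- simulate_session(prof, cfg)
  frac <- mean(sess$labels %in% ARTIFACT_CODES)
  expect_lt(abs(frac - 0.05), 0.01)
  expect_true(all(sess$labels[sess$labels < 0] %in% ARTIFACT_CODES))

  cfg0 <- generator_config(n_subjects = 1L, phasic_reps = 5L,
                           artifact_fraction = 0)
  set.seed(9)
  sess0 <- simulate_session(subject_profile("S1"), cfg0)
  labels_before <- sess0$labels
  expect_identical(inject_artifacts(sess0, cfg0)$labels, labels_before)
})

test_that("session files round-trip through CSV", {
  set.seed(2)
  cfg <- tiny_config()
  sess <- simulate_session(subject_profile("S9"), cfg)
  path <- tempfile(fileext = ".csv")
  write_session_csv(sess, path)
  back <- read_session_csv(path)
  expect_equal(back$sampling_rate_hz, 25)
  expect_equal(back$labels, sess$labels)
  expect_equal(back$eda, sess$eda, tolerance = 1e-6)
  expect_equal(ncol(back$facial), 21L)
  unlink(path)
})
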