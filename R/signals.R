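#' Skin-conductance response kernel
#'
#' Canonical rise-decay shape modelled as a difference of two exponentials,
#' `k(t) = exp(-t/decay) - exp(-t/rise)` for `t >= 0`, scaled so its peak is
#' exactly 1. The peak occurs at
#' `t* = rise * decay / (decay - rise) * log(decay / rise)`.
#'
#' @param t numeric vector of times (seconds) relative to response onset
#' @param rise_s rise time constant (s)
#' @param decay_s decay time constant (s), must exceed `rise_s`
#' @return kernel values, 0 for `t < 0`
#' @export
scr_kernel <- function(t, rise_s = 0.75, decay_s = 4) {
  stopifnot(decay_s > rise_s, rise_s > 0)
  pk <- scr_kernel_peak_time(rise_s, decay_s)
  peak <- exp(-pk / decay_s) - exp(-pk / rise_s)
  out <- ifelse(t >= 0, (exp(-t / decay_s) - exp(-t / rise_s)) / peak, 0)
  out
}

#' @rdname scr_kernel
#' @export
scr_kernel_peak_time <- function(rise_s = 0.75, decay_s = 4) {
  rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
}

# Normalized cumulative of the raw difference-of-exponentials kernel;
# saturates at 1, used to build sustained plateaus for long stimuli.
scr_cumulative <- function(t, rise_s, decay_s) {
  ifelse(t >= 0,
         (decay_s * (1 - exp(-t / decay_s)) -
            rise_s * (1 - exp(-t / rise_s))) / (decay_s - rise_s),
         0)
}

# Add one event's response to `series` in place-ish; phasic events get the
# peak-normalized kernel, long events a rise/hold/decay plateau of the same
# time constants. Only the local support of the response is touched.
add_response <- function(series, rate, onset_s, duration_s, amp, latency_s,
                         rise_s, decay_s, sustained) {
  n <- length(series)
  t_start <- onset_s + latency_s
  i0 <- max(0L, floor(t_start * rate))
  i1 <- min(n - 1L, ceiling((t_start + duration_s + 10 * decay_s) * rate))
  if (i1 < i0) return(series)
  idx <- i0:i1
  tt <- idx / rate - t_start
  resp <- if (sustained) {
    amp * (scr_cumulative(tt, rise_s, decay_s) -
             scr_cumulative(tt - duration_s, rise_s, decay_s))
  } else {
    amp * scr_kernel(tt, rise_s, decay_s)
  }
  series[idx + 1L] <- series[idx + 1L] + resp
  series
}

#' Synthesize an electrodermal activity channel
#'
#' The series is the sum of a slow tonic component (baseline level plus a
#' slow sinusoidal drift), one stimulus-locked skin-conductance response per
#' scheduled event, and i.i.d. Gaussian noise. Each response starts
#' `scr_latency_s` after stimulus onset with peak amplitude
#' `eda_gain * intensity * (1 + jitter)`; tonic (60 s) stimuli produce a
#' sustained plateau over their duration instead of a transient peak.
#'
#' @param schedule a `stim_schedule`
#' @param profile a [subject_profile()]
#' @param cfg a [generator_config()]
#' @return numeric vector of length `ceil(session_duration * rate)`
#' @export
synthesize_eda <- function(schedule, profile, cfg) {
  rate <- cfg$sampling_rate_hz
  n <- ceiling(attr(schedule, "session_duration_s") * rate)
  tt <- (seq_len(n) - 1) / rate
  series <- profile$baseline_eda +
    profile$drift_amp * sin(2 * pi * tt / profile$drift_period_s +
                              profile$drift_phase)
  for (k in seq_len(nrow(schedule))) {
    amp <- profile$eda_gain * schedule$intensity[k] *
      max(0.2, 1 + stats::rnorm(1, 0, profile$amp_jitter))
    series <- add_response(series, rate,
                           schedule$onset_s[k], schedule$duration_s[k],
                           amp, profile$scr_latency_s,
                           profile$scr_rise_s, profile$scr_decay_s,
                           sustained = schedule$stim_type[k] == "tonic")
  }
  if (profile$noise_sd > 0)
    series <- series + stats::rnorm(n, 0, profile$noise_sd)
  series
}

#' Indices of the facial channels that respond to pain
#'
#' Of the 21 facial channels (3 head-pose plus 18 action-unit channels), a
#' fixed subset stands in for the pain-related action units (brow lowerer,
#' orbit tightening, levator, lid tightener and companions); the remaining
#' channels carry only noise.
#'
#' @return integer vector of channel indices (1-based)
#' @export
facial_responsive_channels <- function() 5:12

# Relative response strength of each responsive channel.
facial_channel_weights <- function() c(1, 0.9, 0.85, 0.75, 0.6, 0.5, 0.4, 0.3)

#' Synthesize the 21 facial-activity channels
#'
#' Pain-responsive channels receive stimulus-locked bumps (a fast rise-decay
#' kernel for phasic stimuli, a sustained plateau for tonic ones) with
#' amplitude `facial_gain * intensity * weight`, delayed by the subject's
#' facial response latency; all channels carry i.i.d. Gaussian noise.
#' Subjects of expressiveness category 1 have `facial_gain = 0` and hence
#' flat responsive channels.
#'
#' @inheritParams synthesize_eda
#' @return numeric matrix, `N x 21`, columns named `f01..f21`
#' @export
synthesize_facial <- function(schedule, profile, cfg) {
  rate <- cfg$sampling_rate_hz
  n <- ceiling(attr(schedule, "session_duration_s") * rate)
  n_ch <- 21L
  resp_ch <- facial_responsive_channels()
  w <- facial_channel_weights()
  base <- matrix(0, n, n_ch)
  if (profile$facial_gain > 0 && nrow(schedule) > 0) {
    track <- numeric(n)
    for (k in seq_len(nrow(schedule))) {
      amp <- profile$facial_gain * schedule$intensity[k] *
        max(0.2, 1 + stats::rnorm(1, 0, profile$amp_jitter))
      track <- add_response(track, rate,
                            schedule$onset_s[k], schedule$duration_s[k],
                            amp, profile$facial_latency_s,
                            rise_s = 0.5, decay_s = 1.5,
                            sustained = schedule$stim_type[k] == "tonic")
    }
    base[, resp_ch] <- outer(track, w)
  }
  if (profile$noise_sd > 0)
    base <- base + matrix(stats::rnorm(n * n_ch, 0, profile$noise_sd), n, n_ch)
  colnames(base) <- sprintf("f%02d", seq_len(n_ch))
  base
}
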