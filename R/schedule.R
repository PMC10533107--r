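#' Generator configuration
#'
#' Describes one simulated stimulation protocol: short (phasic, 5 s) stimuli
#' repeated many times in randomized order with short pauses, and long
#' (tonic, 60 s) stimuli applied once per quality and intensity with long
#' pauses, for two stimulus qualities (heat, electrical) at three
#' intensities. Defaults mirror the protocol of the experimental database the
#' generator emulates: 30 phasic repetitions per (quality, intensity) with
#' pauses drawn uniformly from 8-12 s, and one 60 s tonic stimulus per
#' (quality, intensity) followed by a 300 s pause, i.e. a session of roughly
#' 80 minutes.
#'
#' @param n_subjects number of subjects in a cohort
#' @param phasic_reps repetitions of each phasic (quality, intensity) pair
#' @param phasic_duration_s phasic stimulus duration, seconds
#' @param phasic_pause_range_s length-2 numeric, uniform range of the pause
#'   after each phasic stimulus
#' @param tonic_reps repetitions of each tonic pair (0 disables tonic block)
#' @param tonic_duration_s tonic stimulus duration, seconds
#' @param tonic_pause_s fixed pause after each tonic stimulus, seconds
#' @param qualities stimulus qualities to include
#' @param intensities stimulus intensities to include
#' @param block_order "phasic_first" or "tonic_first"; how the two stimulus
#'   blocks are concatenated (the protocol's true interleaving is not public,
#'   so it is a configuration choice; dataset filters key on label codes and
#'   are insensitive to it)
#' @param lead_in_s baseline seconds before the first stimulus
#' @param tail_s baseline seconds appended after the last pause so that
#'   trailing windows exist
#' @param artifact_fraction fraction of samples whose labels are overwritten
#'   with artifact codes, in `[0, 1)`
#' @param split_fractions length-3 numeric (train, validation, test) subject
#'   fractions, summing to 1
#' @param sampling_rate_hz sampling rate of all channels
#' @param eda_gain_mean mean skin-conductance response amplitude per
#'   intensity unit, microsiemens
#' @param noise_sd per-channel Gaussian noise standard deviation
#' @param seed integer seed used by [generate_cohort()]
#' @return a validated list of class `"generator_config"`
#' @export
generator_config <- function(n_subjects = 10L,
                             phasic_reps = 30L,
                             phasic_duration_s = 5,
                             phasic_pause_range_s = c(8, 12),
                             tonic_reps = 1L,
                             tonic_duration_s = 60,
                             tonic_pause_s = 300,
                             qualities = c("heat", "electrical"),
                             intensities = 1:3,
                             block_order = c("phasic_first", "tonic_first"),
                             lead_in_s = 10,
                             tail_s = 10,
                             artifact_fraction = 0.02,
                             split_fractions = c(0.8, 0.1, 0.1),
                             sampling_rate_hz = 25,
                             eda_gain_mean = 0.3,
                             noise_sd = 0.05,
                             seed = 1L) {
  block_order <- match.arg(block_order)
  cfg <- list(n_subjects = as.integer(n_subjects),
              phasic_reps = as.integer(phasic_reps),
              phasic_duration_s = phasic_duration_s,
              phasic_pause_range_s = phasic_pause_range_s,
              tonic_reps = as.integer(tonic_reps),
              tonic_duration_s = tonic_duration_s,
              tonic_pause_s = tonic_pause_s,
              qualities = qualities,
              intensities = as.integer(intensities),
              block_order = block_order,
              lead_in_s = lead_in_s,
              tail_s = tail_s,
              artifact_fraction = artifact_fraction,
              split_fractions = split_fractions,
              sampling_rate_hz = sampling_rate_hz,
              eda_gain_mean = eda_gain_mean,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$phasic_reps < 0L || cfg$tonic_reps < 0L)
    stop("stimulus repetition counts must be non-negative", call. = FALSE)
  if (cfg$phasic_duration_s <= 0 || cfg$tonic_duration_s <= 0)
    stop("stimulus durations must be positive", call. = FALSE)
  if (length(cfg$phasic_pause_range_s) != 2L ||
      diff(cfg$phasic_pause_range_s) < 0 || any(cfg$phasic_pause_range_s < 0))
    stop("phasic_pause_range_s must be an increasing non-negative range",
         call. = FALSE)
  if (cfg$artifact_fraction < 0 || cfg$artifact_fraction >= 1)
    stop("artifact_fraction must lie in [0, 1)", call. = FALSE)
  if (length(cfg$split_fractions) != 3L ||
      abs(sum(cfg$split_fractions) - 1) > 1e-8 || any(cfg$split_fractions <= 0))
    stop("split_fractions must be three positive numbers summing to 1",
         call. = FALSE)
  if (!all(cfg$qualities %in% c("heat", "electrical")) ||
      !length(cfg$qualities))
    stop("qualities must be a subset of heat/electrical", call. = FALSE)
  if (!all(cfg$intensities %in% 1:3) || !length(cfg$intensities))
    stop("intensities must be a subset of 1:3", call. = FALSE)
  if (cfg$sampling_rate_hz <= 0) stop("sampling rate must be positive",
                                      call. = FALSE)
  invisible(cfg)
}

#' Generate a randomized stimulation schedule
#'
#' Lays out one session: every phasic (quality, intensity) pair repeated
#' `phasic_reps` times in globally randomized order with uniform pauses, then
#' (by default) every tonic pair once, in randomized order, each followed by
#' the long tonic pause. Events never overlap. Uses the current RNG state;
#' seed the generator (`set.seed`) for reproducibility.
#'
#' @param cfg a [generator_config()]
#' @return data.frame of class `"stim_schedule"` with columns `onset_s`,
#'   `duration_s`, `stim_type`, `quality`, `intensity`, `code`, plus
#'   attribute `session_duration_s`.
#' @export
generate_schedule <- function(cfg) {
  validate_generator_config(cfg)
  combos <- expand.grid(quality = cfg$qualities,
                        intensity = cfg$intensities,
                        stringsAsFactors = FALSE)

  make_block <- function(stim_type, reps, duration, pause_fun) {
    if (reps == 0L || nrow(combos) == 0L)
      return(list(events = NULL, span = 0))
    ev <- combos[rep(seq_len(nrow(combos)), each = reps), , drop = FALSE]
    ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
    pauses <- pause_fun(nrow(ev))
    onsets <- cumsum(c(0, head(duration + pauses, -1)))
    events <- data.frame(onset_s = onsets,
                         duration_s = duration,
                         stim_type = stim_type,
                         quality = ev$quality,
                         intensity = as.integer(ev$intensity),
                         stringsAsFactors = FALSE)
    list(events = events, span = sum(duration + pauses))
  }

  phasic <- make_block("phasic", cfg$phasic_reps, cfg$phasic_duration_s,
                       function(n) stats::runif(n, cfg$phasic_pause_range_s[1],
                                                cfg$phasic_pause_range_s[2]))
  tonic <- make_block("tonic", cfg$tonic_reps, cfg$tonic_duration_s,
                      function(n) rep(cfg$tonic_pause_s, n))

  blocks <- if (cfg$block_order == "phasic_first") list(phasic, tonic)
            else list(tonic, phasic)
  t0 <- cfg$lead_in_s
  out <- NULL
  for (b in blocks) {
    if (!is.null(b$events)) {
      b$events$onset_s <- b$events$onset_s + t0
      out <- rbind(out, b$events)
      t0 <- t0 + b$span
    }
  }
  if (is.null(out)) {
    out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      stim_type = character(0), quality = character(0),
                      intensity = integer(0), code = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out$code <- pain_code(out$stim_type, out$quality, out$intensity)
  }
  rownames(out) <- NULL
  attr(out, "session_duration_s") <- t0 + cfg$tail_s
  class(out) <- c("stim_schedule", "data.frame")
  out
}

#' Per-sample label stream implied by a schedule
#'
#' Sample `i` (0-based) covers time `i / rate`; it carries the code of the
#' event whose `[onset, onset + duration)` interval contains that time, and
#' the baseline code otherwise.
#'
#' @param schedule a `stim_schedule`
#' @param n_samples total number of samples
#' @param rate sampling rate, Hz
#' @return integer label vector of length `n_samples`
#' @export
schedule_labels <- function(schedule, n_samples, rate = 25) {
  labels <- rep(BL_CODE, n_samples)
  for (k in seq_len(nrow(schedule))) {
    i0 <- ceiling(schedule$onset_s[k] * rate)
    i1 <- ceiling((schedule$onset_s[k] + schedule$duration_s[k]) * rate) - 1L
    i0 <- max(i0, 0L); i1 <- min(i1, n_samples - 1L)
    if (i1 >= i0) labels[(i0:i1) + 1L] <- schedule$code[k]
  }
  labels
}
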