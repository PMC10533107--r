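#' Subject profile
#'
#' Per-subject generative parameters. The expressiveness category (1-4)
#' controls the facial response strength: category 1 means no facial
#' response to pain, category 4 an intensive one; the facial gain is
#' non-decreasing in the category and exactly zero for category 1.
#'
#' @param subject_id character id
#' @param expressiveness_category integer 1-4
#' @param eda_gain skin-conductance response amplitude per intensity unit
#'   (microsiemens), positive
#' @param facial_gain facial bump amplitude per intensity unit; must be 0
#'   for category 1
#' @param scr_latency_s response latency of the EDA channel, in `[1, 3]` s
#' @param noise_sd Gaussian noise sd applied to every channel
#' @param facial_latency_s latency of the facial response (defaults near the
#'   2-3 s delay the downstream label shift compensates)
#' @param baseline_eda tonic skin-conductance level (microsiemens)
#' @param drift_amp,drift_period_s,drift_phase slow sinusoidal drift of the
#'   tonic EDA level
#' @param scr_rise_s,scr_decay_s SCR kernel time constants
#' @param amp_jitter sd of the multiplicative per-event amplitude jitter
#' @return list of class `"subject_profile"`
#' @export
subject_profile <- function(subject_id,
                            expressiveness_category = 3L,
                            eda_gain = 0.3,
                            facial_gain = 0.4 * (expressiveness_category - 1),
                            scr_latency_s = 2,
                            noise_sd = 0.05,
                            facial_latency_s = 2,
                            baseline_eda = 2,
                            drift_amp = 0.3,
                            drift_period_s = 900,
                            drift_phase = 0,
                            scr_rise_s = 0.75,
                            scr_decay_s = 4,
                            amp_jitter = 0.1) {
  stopifnot(expressiveness_category %in% 1:4,
            eda_gain >= 0, facial_gain >= 0, noise_sd >= 0,
            scr_latency_s >= 1, scr_latency_s <= 3,
            is.finite(eda_gain), is.finite(facial_gain), is.finite(noise_sd))
  if (expressiveness_category == 1L && facial_gain != 0)
    stop("category-1 subjects must have facial_gain 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 expressiveness_category = as.integer(expressiveness_category),
                 eda_gain = eda_gain, facial_gain = facial_gain,
                 scr_latency_s = scr_latency_s, noise_sd = noise_sd,
                 facial_latency_s = facial_latency_s,
                 baseline_eda = baseline_eda, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, drift_phase = drift_phase,
                 scr_rise_s = scr_rise_s, scr_decay_s = scr_decay_s,
                 amp_jitter = amp_jitter),
            class = "subject_profile")
}

#' Simulate one full pain session for a subject
#'
#' Draws a schedule, synthesizes the EDA and facial channels, derives the
#' per-sample label stream and injects artifact labels. Uses the current
#' RNG state.
#'
#' @param profile a [subject_profile()]
#' @param cfg a [generator_config()]
#' @return list of class `"pain_session"` with elements `subject_id`,
#'   `sampling_rate_hz`, `eda` (numeric N), `facial` (N x 21 matrix),
#'   `labels` (integer N), `schedule`, `profile`.
#' @export
simulate_session <- function(profile, cfg) {
  schedule <- generate_schedule(cfg)
  rate <- cfg$sampling_rate_hz
  n <- ceiling(attr(schedule, "session_duration_s") * rate)
  eda <- synthesize_eda(schedule, profile, cfg)
  facial <- synthesize_facial(schedule, profile, cfg)
  labels <- schedule_labels(schedule, n, rate)
  session <- structure(list(subject_id = profile$subject_id,
                            sampling_rate_hz = rate,
                            eda = eda, facial = facial,
                            labels = labels, schedule = schedule,
                            profile = profile),
                       class = "pain_session")
  inject_artifacts(session, cfg)
}

#' @export
print.pain_session <- function(x, ...) {
  cat(sprintf("<pain_session> subject %s: %d samples @ %g Hz (%.1f min), %d events, %.2f%% artifact samples\n",
              x$subject_id, length(x$labels), x$sampling_rate_hz,
              length(x$labels) / x$sampling_rate_hz / 60,
              nrow(x$schedule),
              100 * mean(x$labels %in% ARTIFACT_CODES)))
  invisible(x)
}

#' Overwrite random label spans with artifact codes
#'
#' Marks non-overlapping spans (1-3 s) with the artifact codes -10/-11 until
#' approximately `cfg$artifact_fraction` of the samples carry an artifact
#' label. Signals are untouched; only the label stream changes.
#'
#' @param session a `pain_session`
#' @param cfg a [generator_config()]
#' @return the session with updated labels
#' @export
inject_artifacts <- function(session, cfg) {
  frac <- cfg$artifact_fraction
  stopifnot(frac >= 0, frac < 1)
  if (frac == 0) return(session)
  n <- length(session$labels)
  rate <- session$sampling_rate_hz
  target <- round(frac * n)
  marked <- rep(FALSE, n)
  placed <- 0L
  tries <- 0L
  while (placed < target && tries < 10000L) {
    tries <- tries + 1L
    len <- min(sample(seq(rate, 3 * rate), 1L), target - placed)
    start <- sample.int(n - len + 1L, 1L)
    span <- start:(start + len - 1L)
    if (any(marked[span])) next
    marked[span] <- TRUE
    session$labels[span] <- sample(ARTIFACT_CODES, 1L)
    placed <- placed + len
  }
  session
}

#' Write / read a session file
#'
#' Columnar CSV with header `time_s, eda, f01..f21, label`; time strictly
#' increasing in steps of `1/rate`.
#'
#' @param session a `pain_session`
#' @param path output file
#' @return `write_session_csv`: the path, invisibly; `read_session_csv`: a
#'   list with `time_s`, `eda`, `facial`, `labels`, `sampling_rate_hz`.
#' @export
write_session_csv <- function(session, path) {
  n <- length(session$labels)
  df <- data.frame(time_s = (seq_len(n) - 1) / session$sampling_rate_hz,
                   eda = session$eda)
  df <- cbind(df, as.data.frame(session$facial))
  df$label <- session$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "eda", "label") %in% names(df)))
  fcols <- grep("^f[0-9]{2}$", names(df), value = TRUE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  list(time_s = df$time_s, eda = df$eda,
       facial = as.matrix(df[, fcols, drop = FALSE]),
       labels = as.integer(df$label),
       sampling_rate_hz = round(1 / stats::median(dt)))
}

#' Generate a cohort of subjects with a train/validation/test split
#'
#' Subjects are assigned to the four expressiveness categories in a balanced
#' round-robin, given randomized generative parameters, and simulated
#' independently. The subject-level split follows `cfg$split_fractions`
#' (approximately 80/10/10 by default), allocated within category strata so
#' the categories are spread across splits as far as the split sizes allow;
#' every split automatically contains all stimulus intensities because every
#' subject receives the full protocol. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [generator_config()]
#' @return list of class `"pain_cohort"`: `sessions` (named list of
#'   `pain_session`) and `manifest` (data.frame with `subject_id`,
#'   `category`, `split`, `seed`).
#' @export
generate_cohort <- function(cfg) {
  validate_generator_config(cfg)
  n <- cfg$n_subjects
  if (n < 3L)
    stop("need at least 3 subjects to populate train/validation/test",
         call. = FALSE)
  set.seed(cfg$seed)
  sizes <- split_sizes(n, cfg$split_fractions)
  categories <- sample(rep_len(1:4, n))
  split <- stratified_split(categories, sizes)

  sessions <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    profile <- subject_profile(
      subject_id = ids[i],
      expressiveness_category = categories[i],
      eda_gain = cfg$eda_gain_mean * stats::rlnorm(1, 0, 0.25),
      facial_gain = 0.4 * (categories[i] - 1) *
        if (categories[i] > 1) stats::rlnorm(1, 0, 0.15) else 1,
      scr_latency_s = stats::runif(1, 1, 3),
      noise_sd = cfg$noise_sd,
      facial_latency_s = stats::runif(1, 1.5, 2.5),
      baseline_eda = stats::runif(1, 1, 4),
      drift_amp = stats::runif(1, 0.1, 0.5),
      drift_phase = stats::runif(1, 0, 2 * pi))
    sessions[[i]] <- simulate_session(profile, cfg)
  }
  names(sessions) <- ids
  manifest <- data.frame(subject_id = ids, category = categories,
                         split = split, seed = cfg$seed,
                         stringsAsFactors = FALSE)
  structure(list(sessions = sessions, manifest = manifest, config = cfg),
            class = "pain_cohort")
}

split_sizes <- function(n, fractions) {
  sizes <- floor(n * fractions)
  sizes <- pmax(sizes, 1L)
  # distribute the remainder by largest fractional part, training first
  while (sum(sizes) < n) sizes[1] <- sizes[1] + 1L
  while (sum(sizes) > n) sizes[1] <- sizes[1] - 1L
  if (any(sizes < 1L))
    stop("too few subjects for a train/validation/test split", call. = FALSE)
  stats::setNames(as.integer(sizes), c("train", "validation", "test"))
}

# Deal subjects to splits within category strata so categories are spread
# across splits as evenly as the quota allows.
stratified_split <- function(categories, sizes) {
  n <- length(categories)
  split <- character(n)
  remaining <- sizes
  # deal subjects category-by-category, always topping up the split with the
  # largest remaining relative deficit
  idx_by_cat <- split(seq_len(n), categories)
  queue <- unlist(lapply(seq_len(max(lengths(idx_by_cat))), function(k) {
    unlist(lapply(idx_by_cat, function(v) if (k <= length(v)) v[k] else NULL))
  }), use.names = FALSE)
  for (i in queue) {
    # fill the split with the largest remaining relative deficit
    tgt <- names(which.max(remaining / sizes))
    split[i] <- tgt
    remaining[tgt] <- remaining[tgt] - 1L
    if (remaining[tgt] == 0L) sizes[tgt] <- Inf # keep ratio finite-safe
  }
  split
}

#' Write a cohort manifest as JSON
#' @param cohort a `pain_cohort`
#' @param path output file
#' @param session_dir optional directory holding per-subject session CSVs
#' @return the path, invisibly
#' @export
write_cohort_manifest <- function(cohort, path, session_dir = NULL) {
  m <- cohort$manifest
  if (!is.null(session_dir))
    m$file <- file.path(session_dir, paste0(m$subject_id, ".csv"))
  jsonlite::write_json(m, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
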