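#' First and second finite differences of a series
#'
#' `d1[i] = x[i+1] - x[i]`; `d2` is the first differences of `d1`.
#'
#' @param x numeric vector, length >= 3
#' @return list with `d1` (length `n - 1`) and `d2` (length `n - 2`)
#' @export
finite_derivatives <- function(x) {
  if (length(x) < 3L)
    stop("need at least 3 samples to form second differences", call. = FALSE)
  d1 <- diff(x)
  list(d1 = d1, d2 = diff(d1))
}

#' Four summary statistics of a series
#'
#' Returns `(min, max, mean, std)` in that fixed order, with the population
#' standard deviation (divide by n).
#'
#' @param x non-empty numeric vector
#' @return named numeric vector of length 4
#' @export
summarize_series <- function(x) {
  if (!length(x)) stop("cannot summarize an empty series", call. = FALSE)
  m <- mean(x)
  c(min = min(x), max = max(x), mean = m,
    std = sqrt(mean((x - m)^2)))
}

# Column-wise (min, max, mean, population sd) of a series cut into
# consecutive groups of `rate` samples (the last group may be shorter).
# Vectorized: the series is padded with NA to a rate x S matrix.
segment_stats <- function(x, n_seconds, rate) {
  total <- n_seconds * rate
  length(x) <- total # pads with NA
  m <- matrix(x, nrow = rate)
  cnt <- colSums(!is.na(m))
  mins <- m[1, ]
  maxs <- m[1, ]
  for (r in seq_len(rate)[-1]) {
    mins <- pmin(mins, m[r, ], na.rm = TRUE)
    maxs <- pmax(maxs, m[r, ], na.rm = TRUE)
  }
  sums <- colSums(m, na.rm = TRUE)
  means <- sums / cnt
  sq <- colSums(m^2, na.rm = TRUE)
  vars <- pmax(sq / cnt - means^2, 0)
  cbind(min = mins, max = maxs, mean = means, std = sqrt(vars))
}

#' Per-second temporal-integration descriptor frames
#'
#' For every whole second of a multichannel 25 Hz recording, computes the
#' four statistics (min, max, mean, population std) of each channel's raw
#' samples and of its first and second finite differences, i.e. 12 features
#' per channel: a 12-dimensional descriptor for a 1-channel EDA series and a
#' 252-dimensional one for the 21 facial channels. Derivatives are taken
#' once over the full series and segmented by the left index of each
#' difference, so the final second has 24 first-difference and 23
#' second-difference samples.
#'
#' @param channels numeric matrix `N x C` (one column per channel; a plain
#'   vector is treated as one channel), sampled at `rate` Hz
#' @param rate sampling rate (samples per second)
#' @return numeric matrix `S x (12 C)` (`S = floor(N / rate)` whole
#'   seconds); columns are channel-major, within channel ordered raw, d1, d2
#'   by (min, max, mean, std)
#' @export
compute_descriptor_frames <- function(channels, rate = 25) {
  if (is.null(dim(channels))) channels <- matrix(channels, ncol = 1)
  n <- nrow(channels)
  if (n < 3 * rate)
    stop("need at least 3 s of samples to compute descriptor frames",
         call. = FALSE)
  n_seconds <- floor(n / rate)
  ch_names <- colnames(channels)
  if (is.null(ch_names)) ch_names <- sprintf("ch%02d", seq_len(ncol(channels)))
  stats_names <- c("min", "max", "mean", "std")
  out <- matrix(NA_real_, n_seconds, 12L * ncol(channels))
  cn <- character(ncol(out))
  for (c in seq_len(ncol(channels))) {
    x <- channels[, c]
    d <- finite_derivatives(x)
    block <- cbind(segment_stats(x, n_seconds, rate),
                   segment_stats(d$d1, n_seconds, rate),
                   segment_stats(d$d2, n_seconds, rate))
    cols <- (c - 1L) * 12L + 1:12
    out[, cols] <- block
    cn[cols] <- paste(ch_names[c], rep(c("raw", "d1", "d2"), each = 4),
                      stats_names, sep = "_")
  }
  colnames(out) <- cn
  out
}

#' Person-specific feature standardization
#'
#' Z-scores every feature column within each subject: subtract the subject's
#' mean and divide by the subject's standard deviation, so models see the
#' within-subject response variation rather than between-subject offsets.
#' Zero-variance features map to 0.
#'
#' @param frames numeric matrix of descriptor frames (rows = seconds)
#' @param subject character/factor vector, one entry per row (a single
#'   string recycles to all rows)
#' @return matrix of the same shape
#' @export
person_standardize <- function(frames, subject) {
  if (length(subject) == 1L) subject <- rep(subject, nrow(frames))
  stopifnot(length(subject) == nrow(frames))
  for (s in unique(subject)) {
    rows <- which(subject == s)
    if (length(rows) < 2L)
      stop("person standardization needs at least 2 frames per subject",
           call. = FALSE)
    block <- frames[rows, , drop = FALSE]
    mu <- colMeans(block)
    sdv <- apply(block, 2, stats::sd)
    z <- sweep(sweep(block, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv == 0] <- 0
    frames[rows, ] <- z
  }
  frames
}

#' Shift a 25 Hz label stream forward in time
#'
#' Facial pain responses lag the stimulus by roughly 2-3 s, so labels are
#' delayed: `shifted[i] = labels[i - rate * shift_s]`, with the first
#' `rate * shift_s` samples set to baseline.
#'
#' @param labels integer label stream
#' @param shift_s non-negative shift in seconds (default 3)
#' @param rate sampling rate
#' @return shifted integer vector of the same length
#' @export
shift_labels <- function(labels, shift_s = 3, rate = 25) {
  stopifnot(shift_s >= 0)
  k <- round(shift_s * rate)
  if (k == 0L || !length(labels)) return(labels)
  n <- length(labels)
  c(rep(BL_CODE, min(k, n)), labels[seq_len(max(0L, n - k))])
}

# Priority used to break ties in the per-second label vote: artifacts beat
# everything, then higher stimulus intensity, then higher code, baseline last.
label_priority <- function(code) {
  info <- decode_label(code)
  ifelse(info$is_artifact, 1e6,
         info$intensity * 100 + pmax(info$code, 0))
}

#' Collapse a 25 Hz label stream to one label per second
#'
#' Each second's label is the mode of its `rate` samples; ties are broken
#' toward the artifact codes first, then toward higher stimulus intensity.
#'
#' @inheritParams shift_labels
#' @return integer vector of length `floor(length(labels) / rate)`
#' @export
second_labels <- function(labels, rate = 25) {
  n_seconds <- floor(length(labels) / rate)
  out <- integer(n_seconds)
  m <- matrix(labels[seq_len(n_seconds * rate)], nrow = rate)
  for (s in seq_len(n_seconds)) {
    tab <- table(m[, s])
    codes <- as.integer(names(tab))
    top <- codes[tab == max(tab)]
    out[s] <- if (length(top) == 1L) top else
      top[which.max(label_priority(top))]
  }
  out
}

#' Assemble 10-s sliding windows of descriptor frames
#'
#' One window per integer second `t` from 10 to `S - 1` (0-based): the
#' features are the 10 consecutive per-second frames covering `[t-10, t)`
#' and the target is the (shifted) label at second `t`. The first ten
#' seconds produce no window because they lack prior observations.
#'
#' @param frames `S x F` matrix of per-second descriptor frames
#' @param sec_labels integer vector of per-second labels (length `S`)
#' @param subject subject id attached to every window
#' @param window_s window length in seconds
#' @return a `window_set`: list with `x` (`n x window_s x F` array), `code`
#'   (integer labels), `subject`, `t_end` (0-based label second), and
#'   `feature_names`
#' @export
build_windows <- function(frames, sec_labels, subject = "S000",
                          window_s = 10L) {
  n_sec <- min(nrow(frames), length(sec_labels))
  if (n_sec < window_s)
    stop("session shorter than ", window_s, " s cannot form windows",
         call. = FALSE)
  # 0-based label seconds; a session of exactly window_s seconds yields an
  # empty (but well-formed) set
  t_end <- seq_len(max(0L, n_sec - window_s)) + window_s - 1L
  n <- length(t_end)
  f <- ncol(frames)
  x <- array(NA_real_, c(n, window_s, f))
  for (j in seq_len(window_s)) {
    # row (t - window_s + j) in 0-based seconds = frame index t - 10 ... t-1
    x[, j, ] <- frames[t_end - window_s + j, , drop = FALSE]
  }
  window_set(x = x, code = sec_labels[t_end + 1L],
             subject = rep(as.character(subject), n), t_end = t_end,
             feature_names = colnames(frames))
}

#' Construct / combine window sets
#'
#' A `window_set` holds aligned windows: a `n x T x F` feature array, the
#' integer label code, subject id and label second of each window.
#'
#' @param x feature array
#' @param code integer labels
#' @param subject character vector
#' @param t_end integer vector of 0-based label seconds
#' @param feature_names optional feature names
#' @return list of class `"window_set"`
#' @export
window_set <- function(x, code, subject, t_end, feature_names = NULL) {
  stopifnot(length(dim(x)) == 3L, dim(x)[1] == length(code),
            length(code) == length(subject), length(code) == length(t_end))
  structure(list(x = x, code = as.integer(code),
                 subject = as.character(subject),
                 t_end = as.integer(t_end),
                 feature_names = feature_names),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<window_set> %d windows of %d x %d (%d subjects)\n",
              d[1], d[2], d[3], length(unique(x$subject))))
  if (!is.null(x$spec)) cat("  dataset:", x$spec$id, "\n")
  invisible(x)
}

#' Number of windows in a set
#' @param ws a `window_set`
#' @return integer count
#' @export
n_windows <- function(ws) dim(ws$x)[1]

#' Subset a window set by window index
#' @param ws a `window_set`
#' @param idx integer or logical index
#' @return a `window_set`
#' @export
subset_windows <- function(ws, idx) {
  if (is.logical(idx)) idx <- which(idx)
  out <- window_set(ws$x[idx, , , drop = FALSE], ws$code[idx],
                    ws$subject[idx], ws$t_end[idx], ws$feature_names)
  out$spec <- ws$spec
  for (fld in c("class_index", "class_label", "value"))
    if (!is.null(ws[[fld]])) out[[fld]] <- ws[[fld]][idx]
  out
}

#' Concatenate window sets
#' @param ... `window_set` objects with identical window shape
#' @return a `window_set`
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  d <- dim(sets[[1]]$x)
  n_tot <- sum(vapply(sets, n_windows, integer(1)))
  x <- array(NA_real_, c(n_tot, d[2], d[3]))
  at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    if (k) x[at + seq_len(k), , ] <- s$x
    at <- at + k
  }
  window_set(x, unlist(lapply(sets, `[[`, "code")),
             unlist(lapply(sets, `[[`, "subject")),
             unlist(lapply(sets, `[[`, "t_end")),
             sets[[1]]$feature_names)
}

#' Full per-session descriptor-and-window pipeline
#'
#' Computes descriptor frames for the chosen modality, standardizes them
#' within the subject, shifts the label stream by `shift_s`, collapses it to
#' per-second labels and assembles sliding windows.
#'
#' @param session a `pain_session`
#' @param modality "eda" (12 features/s) or "facial" (252 features/s)
#' @param shift_s label shift in seconds
#' @param window_s window length in seconds
#' @param standardize apply person standardization (default TRUE)
#' @return a `window_set`
#' @export
session_windows <- function(session, modality = c("eda", "facial"),
                            shift_s = 3, window_s = 10L,
                            standardize = TRUE) {
  modality <- match.arg(modality)
  rate <- session$sampling_rate_hz
  channels <- if (modality == "eda") {
    matrix(session$eda, ncol = 1, dimnames = list(NULL, "eda"))
  } else session$facial
  frames <- compute_descriptor_frames(channels, rate)
  if (standardize)
    frames <- person_standardize(frames, session$subject_id)
  shifted <- shift_labels(session$labels, shift_s, rate)
  sec <- second_labels(shifted, rate)
  ws <- build_windows(frames, sec, session$subject_id, window_s)
  ws
}
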