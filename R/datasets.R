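#' Specifications of the 11 named datasets
#'
#' Each dataset keeps one stimulus type (phasic or tonic), optionally one
#' quality (heat or electrical), and is either full or "reduced" (the
#' no-pain windows preceding each pain sequence are trimmed to the sequence
#' length). Seven-class datasets keep both qualities; four-class datasets
#' keep one. There is no reduced heat tonic dataset: the heat tonic dataset
#' is already close to balanced.
#'
#' @param id one of PD, HPD, EPD, TD, HTD, ETD, RPD, RHPD, REPD, RTD, RETD
#' @return list of class `"dataset_spec"` with fields `id`, `stim_type`,
#'   `quality`, `n_classes`, `reduced`
#' @export
dataset_spec <- function(id) {
  specs <- list(
    PD   = list(stim_type = "phasic", quality = "both", reduced = FALSE),
    HPD  = list(stim_type = "phasic", quality = "heat", reduced = FALSE),
    EPD  = list(stim_type = "phasic", quality = "electrical", reduced = FALSE),
    TD   = list(stim_type = "tonic",  quality = "both", reduced = FALSE),
    HTD  = list(stim_type = "tonic",  quality = "heat", reduced = FALSE),
    ETD  = list(stim_type = "tonic",  quality = "electrical", reduced = FALSE),
    RPD  = list(stim_type = "phasic", quality = "both", reduced = TRUE),
    RHPD = list(stim_type = "phasic", quality = "heat", reduced = TRUE),
    REPD = list(stim_type = "phasic", quality = "electrical", reduced = TRUE),
    RTD  = list(stim_type = "tonic",  quality = "both", reduced = TRUE),
    RETD = list(stim_type = "tonic",  quality = "electrical", reduced = TRUE))
  if (!id %in% names(specs))
    stop("unknown dataset id: ", id, call. = FALSE)
  s <- specs[[id]]
  s$id <- id
  s$n_classes <- if (s$quality == "both") 7L else 4L
  class(s) <- "dataset_spec"
  s
}

#' @rdname dataset_spec
#' @export
dataset_ids <- function() c("PD", "HPD", "EPD", "TD", "HTD", "ETD",
                            "RPD", "RHPD", "REPD", "RTD", "RETD")

# Per-subject runs of identical label codes, in time order.
label_runs <- function(codes) {
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  data.frame(code = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' Filter windows into one dataset
#'
#' Drops artifact-labelled windows, keeps only the pain sequences matching
#' the dataset's stimulus type and quality, and attributes each run of
#' no-pain (baseline) windows to the immediately following pain sequence:
#' baseline runs attached to excluded sequences are dropped, as is the
#' baseline after the last retained sequence. Operates per subject on
#' time-ordered windows.
#'
#' @param ws a `window_set`
#' @param spec a [dataset_spec()] or dataset id string
#' @return the filtered `window_set` with the spec attached
#' @export
filter_windows <- function(ws, spec) {
  if (is.character(spec)) spec <- dataset_spec(spec)
  stopifnot(inherits(spec, "dataset_spec"))
  keep <- logical(n_windows(ws))
  for (s in unique(ws$subject)) {
    rows <- which(ws$subject == s)
    rows <- rows[order(ws$t_end[rows])]
    codes <- ws$code[rows]
    ok <- !codes %in% ARTIFACT_CODES
    sub <- rows[ok]
    if (!length(sub)) next
    info <- decode_label(ws$code[sub])
    runs <- label_runs(ws$code[sub])
    pending_bl <- integer(0)
    for (k in seq_len(nrow(runs))) {
      span <- runs$start[k]:runs$end[k]
      if (runs$code[k] == BL_CODE) {
        pending_bl <- span
      } else {
        matches <- info$stim_type[span[1]] == spec$stim_type &&
          (spec$quality == "both" || info$quality[span[1]] == spec$quality)
        if (matches) keep[sub[c(pending_bl, span)]] <- TRUE
        pending_bl <- integer(0)
      }
    }
  }
  out <- subset_windows(ws, keep)
  out$spec <- spec
  out
}

#' Reduce the no-pain windows of a filtered dataset
#'
#' For each pain sequence of `m` windows, only the `m` no-pain windows
#' immediately preceding it are retained; earlier windows of that baseline
#' run are discarded. Sequences preceded by fewer than `m` baseline windows
#' keep all of them. Pain windows are never touched, so on streams where
#' every sequence has enough preceding baseline the result is exactly 50%
#' no-pain.
#'
#' @param ws a filtered `window_set` whose spec has `reduced = TRUE`
#' @return the reduced `window_set`
#' @export
reduce_no_pain <- function(ws) {
  spec <- ws$spec
  if (is.null(spec) || !isTRUE(spec$reduced))
    stop("reduce_no_pain requires a window set filtered with a reduced spec",
         call. = FALSE)
  keep <- logical(n_windows(ws))
  for (s in unique(ws$subject)) {
    rows <- which(ws$subject == s)
    rows <- rows[order(ws$t_end[rows])]
    runs <- label_runs(ws$code[rows])
    for (k in seq_len(nrow(runs))) {
      span <- runs$start[k]:runs$end[k]
      if (runs$code[k] != BL_CODE) {
        keep[rows[span]] <- TRUE
      } else if (k < nrow(runs) && runs$code[k + 1L] != BL_CODE) {
        m <- runs$end[k + 1L] - runs$start[k + 1L] + 1L
        kept <- utils::tail(span, m)
        keep[rows[kept]] <- TRUE
      }
    }
  }
  subset_windows(ws, keep)
}

#' Encode dataset labels as class indices and continuous targets
#'
#' Class ordering: 7-class datasets use (BL, heat 1-3, electrical 1-3) =
#' indices 0-6; 4-class datasets use (BL, intensity 1-3) = indices 0-3. The
#' continuous target normalizes intensity to `[0, 1]`: baseline 0, low 1/3,
#' moderate 2/3, severe 1; quality is ignored for the continuous target.
#'
#' @param ws a filtered (optionally reduced) `window_set` with a spec
#' @return the `window_set` with `class_index` (0-based integer),
#'   `class_label` (character) and `value` (numeric target) fields added
#' @export
encode_labels <- function(ws) {
  spec <- ws$spec
  if (is.null(spec))
    stop("encode_labels requires a window set with a dataset spec",
         call. = FALSE)
  info <- decode_label(ws$code)
  if (any(info$is_artifact))
    stop("artifact windows must be filtered out before encoding",
         call. = FALSE)
  bad <- info$is_pain &
    (info$stim_type != spec$stim_type |
       (spec$quality != "both" & info$quality != spec$quality))
  if (any(bad))
    stop("window codes outside the dataset spec", call. = FALSE)
  idx <- integer(n_windows(ws))
  if (spec$n_classes == 7L) {
    idx[info$is_pain] <- ifelse(info$quality[info$is_pain] == "heat",
                                info$intensity[info$is_pain],
                                3L + info$intensity[info$is_pain])
  } else {
    idx[info$is_pain] <- info$intensity[info$is_pain]
  }
  ws$class_index <- idx
  ws$class_label <- label_name(ws$code)
  ws$value <- info$intensity / 3
  ws
}

#' Class labels of a dataset spec, in index order
#' @param spec a [dataset_spec()] or id
#' @return character vector of length `n_classes`
#' @export
dataset_classes <- function(spec) {
  if (is.character(spec)) spec <- dataset_spec(spec)
  p <- if (spec$stim_type == "phasic") "P" else "T"
  if (spec$n_classes == 7L)
    c("BL", paste0(p, "H", 1:3), paste0(p, "E", 1:3))
  else
    c("BL", paste0(p, ifelse(spec$quality == "heat", "H", "E"), 1:3))
}

#' Build one named dataset from a window set
#'
#' Convenience wrapper: filter, reduce if the spec requires it, and encode.
#'
#' @param ws a `window_set` (one split, time-ordered per subject)
#' @param id dataset id
#' @return an encoded `window_set`
#' @export
build_dataset <- function(ws, id) {
  out <- filter_windows(ws, id)
  if (out$spec$reduced) out <- reduce_no_pain(out)
  encode_labels(out)
}

#' Per-class window counts of an encoded dataset
#' @param ws an encoded `window_set`
#' @return named integer vector over the spec's classes
#' @export
class_counts <- function(ws) {
  cls <- dataset_classes(ws$spec)
  cnt <- table(factor(ws$class_label, levels = cls))
  stats::setNames(as.integer(cnt), cls)
}
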