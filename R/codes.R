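#' Label codes for stimulus classes
#'
#' Integer codes used in the per-sample label stream. Baseline (no pain) is 0;
#' the twelve pain classes are coded by stimulus type, quality and intensity;
#' two negative codes mark experimental artifacts whose samples are excluded
#' from every dataset.
#'
#' @format Constants / small helpers, no data object.
#' @name label-codes
NULL

#' Baseline (no-pain) label code
#' @rdname label-codes
#' @export
BL_CODE <- 0L

#' Artifact label codes
#' @rdname label-codes
#' @export
ARTIFACT_CODES <- c(-10L, -11L)

#' Map a stimulus to its integer label code
#'
#' Codes: phasic heat 1-3, phasic electrical 4-6, tonic heat 7-9,
#' tonic electrical 10-12 (the trailing digit is the intensity).
#'
#' @param stim_type "phasic" or "tonic"
#' @param quality "heat" or "electrical"
#' @param intensity integer 1, 2 or 3
#' @return integer code
#' @export
pain_code <- function(stim_type, quality, intensity) {
  stopifnot(all(stim_type %in% c("phasic", "tonic")),
            all(quality %in% c("heat", "electrical")),
            all(intensity %in% 1:3))
  base <- ifelse(stim_type == "phasic", 0L, 6L) +
    ifelse(quality == "heat", 0L, 3L)
  as.integer(base + intensity)
}

#' Decode label codes into stimulus attributes
#'
#' @param code integer vector of label codes
#' @return data.frame with columns `code`, `stim_type`, `quality`,
#'   `intensity`, `is_pain`, `is_artifact`. Baseline and artifact codes get
#'   `NA` stimulus attributes and intensity 0.
#' @export
decode_label <- function(code) {
  code <- as.integer(code)
  is_pain <- code >= 1L & code <= 12L
  is_artifact <- code %in% ARTIFACT_CODES
  stim_type <- ifelse(is_pain, ifelse(code <= 6L, "phasic", "tonic"), NA)
  quality <- ifelse(is_pain,
                    ifelse(((code - 1L) %% 6L) < 3L, "heat", "electrical"),
                    NA)
  intensity <- ifelse(is_pain, ((code - 1L) %% 3L) + 1L, 0L)
  data.frame(code = code, stim_type = stim_type, quality = quality,
             intensity = as.integer(intensity), is_pain = is_pain,
             is_artifact = is_artifact, stringsAsFactors = FALSE)
}

#' Human-readable class label for a code ("BL", "PH1", ..., "TE3")
#' @param code integer vector of label codes
#' @return character vector
#' @export
label_name <- function(code) {
  info <- decode_label(code)
  out <- rep(NA_character_, length(code))
  out[info$code == BL_CODE] <- "BL"
  out[info$is_artifact] <- paste0("ART", info$code[info$is_artifact])
  p <- info$is_pain
  out[p] <- paste0(ifelse(info$stim_type[p] == "phasic", "P", "T"),
                   ifelse(info$quality[p] == "heat", "H", "E"),
                   info$intensity[p])
  out
}
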