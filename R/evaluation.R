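#' Micro-averaged F1 score over the pain classes
#'
#' Precision and recall are pooled over the pain classes only; the no-pain
#' (baseline) class is excluded from the pooling, so a predictor that always
#' votes no-pain scores exactly 0. A baseline prediction on a pain window
#' counts as a pooled false negative, a pain prediction on a baseline window
#' as a pooled false positive.
#'
#' @param pred,truth vectors of class indices (0 = baseline) or labels
#'   ("BL" = baseline), equal length
#' @param bl the baseline class value (default `0`; use `"BL"` for labels)
#' @return F1 as a percentage in `[0, 100]` (`NaN` if neither vector
#'   contains a pain class)
#' @export
micro_f1 <- function(pred, truth, bl = 0L) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length", call. = FALSE)
  pain_classes <- setdiff(unique(c(pred, truth)), bl)
  tp <- fp <- fn <- 0L
  for (cl in pain_classes) {
    tp <- tp + sum(pred == cl & truth == cl)
    fp <- fp + sum(pred == cl & truth != cl)
    fn <- fn + sum(truth == cl & pred != cl)
  }
  if (tp + fp + fn == 0L) return(NaN)
  100 * 2 * tp / (2 * tp + fp + fn)
}

#' Mean squared error of normalized predictions
#'
#' @param pred,truth numeric vectors in `[0, 1]`, equal length
#' @return mean of squared differences
#' @export
mse_norm <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length", call. = FALSE)
  mean((pred - truth)^2)
}

#' Intraclass correlation coefficient ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-rater ICC for k = 2 raters
#' (prediction and ground truth), computed from the two-way ANOVA
#' decomposition with rows = observations and columns = raters:
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE)` where MSR is the between-row
#' mean square and MSE the residual mean square. Equals 1 when `y = x + c`
#' and exactly 0 when one rater is constant.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return ICC in `[-1, 1]`, or `NA` (with a warning) when both vectors are
#'   constant
#' @export
icc_3_1 <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("ICC undefined: both raters are constant")
    return(NA_real_)
  }
  k <- 2
  m <- cbind(x, y)
  gm <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - gm)^2)
  ssc <- n * sum((col_means - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Map class indices to normalized continuous targets
#'
#' Baseline maps to 0; pain classes map to `intensity / 3` ignoring quality
#' (in 7-class datasets indices 1-3 are heat 1-3 and 4-6 electrical 1-3, so
#' both qualities at intensity 2 map to 2/3).
#'
#' @param class_index 0-based class indices
#' @param n_classes 4 or 7
#' @return numeric vector in `[0, 1]`
#' @export
class_to_value <- function(class_index, n_classes) {
  stopifnot(n_classes %in% c(4L, 7L))
  intensity <- if (n_classes == 7L)
    ifelse(class_index == 0L, 0L, (class_index - 1L) %% 3L + 1L)
  else class_index
  intensity / 3
}

#' Continuous values of a prediction set
#'
#' Regression predictions are returned as-is; classification predictions
#' are mapped through the predicted class's normalized intensity, matching
#' the label encoding.
#'
#' @param pred a `prediction_set`
#' @param n_classes class count of the dataset (classification only)
#' @return numeric vector in `[0, 1]`
#' @export
prediction_values <- function(pred, n_classes = NULL) {
  if (pred$task == "regression") return(pred$values)
  if (is.null(n_classes)) n_classes <- ncol(pred$scores)
  class_to_value(predicted_class(pred), n_classes)
}

#' Evaluate one prediction set against an encoded window set
#'
#' Computes the micro-averaged F1 over pain classes (classification only),
#' and MSE and ICC(3,1) on the normalized continuous scale (classification
#' predictions are first mapped to `intensity / 3`).
#'
#' @param pred a `prediction_set`
#' @param ws the encoded `window_set` holding the ground truth
#' @return list with `micro_f1` (NA for regression), `mse`, `icc`,
#'   `n_windows`
#' @export
evaluate_predictions <- function(pred, ws) {
  stopifnot(n_predictions(pred) == n_windows(ws))
  n_classes <- ws$spec$n_classes
  f1 <- if (pred$task == "classification")
    micro_f1(predicted_class(pred), ws$class_index) else NA_real_
  vals <- prediction_values(pred, n_classes)
  icc <- if (stats::var(vals) == 0 && stats::var(ws$value) == 0) NA_real_
         else icc_3_1(vals, ws$value)
  list(micro_f1 = f1, mse = mse_norm(vals, ws$value), icc = icc,
       n_windows = n_windows(ws))
}

#' Assemble an evaluation report over datasets, models and modalities
#'
#' One row per (dataset, model, modality) cell plus a trivial-baseline row
#' per (dataset, task), mirroring the layout of the standard comparison
#' tables.
#'
#' @param cells list of cells; each cell is a list with `dataset`, `model`,
#'   `modality`, `pred` (a `prediction_set`), `truth` (encoded
#'   `window_set`), and optional `lr`, `epochs`, `arch`
#' @param add_trivial add a Trivial row per dataset/task combination present
#' @return data.frame of class `"evaluation_report"` with columns
#'   `dataset`, `model`, `modality`, `task`, `arch`, `lr`,
#'   `micro_f1_percent`, `mse`, `icc`, `n_windows`
#' @export
evaluation_report <- function(cells, add_trivial = TRUE) {
  row_of <- function(dataset, model, modality, pred, truth,
                     arch = NA, lr = NA) {
    m <- evaluate_predictions(pred, truth)
    data.frame(dataset = dataset, model = model, modality = modality,
               task = pred$task, arch = as.character(arch), lr = lr,
               micro_f1_percent = m$micro_f1, mse = m$mse, icc = m$icc,
               n_windows = m$n_windows, stringsAsFactors = FALSE)
  }
  rows <- lapply(cells, function(cl) {
    row_of(cl$dataset, cl$model, cl$modality, cl$pred, cl$truth,
           arch = if (is.null(cl$arch)) NA else cl$arch,
           lr = if (is.null(cl$lr)) NA else cl$lr)
  })
  out <- do.call(rbind, rows)
  if (add_trivial && length(cells)) {
    seen <- unique(do.call(rbind, lapply(cells, function(cl)
      data.frame(dataset = cl$dataset, task = cl$pred$task,
                 stringsAsFactors = FALSE))))
    for (i in seq_len(nrow(seen))) {
      cl <- cells[[which(vapply(cells, function(c0)
        c0$dataset == seen$dataset[i] && c0$pred$task == seen$task[i],
        logical(1)))[1]]]
      triv <- trivial_predictor(n_windows(cl$truth), seen$task[i],
                                dataset_classes(cl$truth$spec))
      out <- rbind(row_of(seen$dataset[i], "Trivial", "-", triv, cl$truth),
                   out)
    }
  }
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Write an evaluation report as CSV and JSON twins
#' @param report an `evaluation_report`
#' @param path_csv,path_json output paths (either may be NULL)
#' @return invisibly, the report
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) utils::write.csv(report, path_csv,
                                           row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
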