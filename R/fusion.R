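#' Decision-level fusion of two modalities
#'
#' Fixed mean-score mapping: for classification the fused score of each
#' class is the mean of the two models' scores and the predicted class is
#' the argmax (ties to the lowest index); for regression the fused value is
#' the elementwise mean of the two predictions. Fusion is symmetric and
#' idempotent and is only meaningful within the same method family (RF with
#' RF, LSTM with LSTM, LSTM-SW with LSTM-SW).
#'
#' @param a,b `prediction_set` objects over the same aligned windows (same
#'   task, same length, same class set)
#' @return a fused `prediction_set` with modality `"DF"`
#' @export
fuse_predictions <- function(a, b) {
  stopifnot(inherits(a, "prediction_set"), inherits(b, "prediction_set"))
  if (a$task != b$task)
    stop("cannot fuse predictions of different tasks", call. = FALSE)
  if (n_predictions(a) != n_predictions(b))
    stop("misaligned prediction sets: window counts differ", call. = FALSE)
  id <- paste0(a$model_id, "+", b$model_id)
  if (a$task == "classification") {
    if (!identical(colnames(a$scores), colnames(b$scores)))
      stop("misaligned prediction sets: class sets differ", call. = FALSE)
    prediction_set("classification", scores = (a$scores + b$scores) / 2,
                   model_id = id, modality = "DF")
  } else {
    prediction_set("regression", values = (a$values + b$values) / 2,
                   model_id = id, modality = "DF")
  }
}
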