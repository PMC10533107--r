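#' Random-forest configuration
#'
#' Baseline ensemble settings: 100 trees with a maximum depth of 10.
#'
#' @param task "classification" or "regression"
#' @param n_trees number of trees
#' @param max_depth maximum tree depth
#' @param seed integer seed (forests are deterministic given the seed)
#' @return list of class `"rf_config"`
#' @export
rf_config <- function(task = c("classification", "regression"),
                      n_trees = 100L, max_depth = 10L, seed = 1L) {
  task <- match.arg(task)
  stopifnot(n_trees >= 1L, max_depth >= 1L)
  structure(list(task = task, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), seed = as.integer(seed)),
            class = "rf_config")
}

#' Flatten a window set to a feature matrix
#'
#' Each `T x F` window becomes one row of `T * F` values (time-major within
#' feature), e.g. 120 features for the 10 x 12 EDA descriptor windows and
#' 2520 for the 10 x 252 facial ones.
#'
#' @param ws a `window_set`
#' @return numeric matrix `n x (T * F)`
#' @export
flatten_windows <- function(ws) {
  d <- dim(ws$x)
  m <- matrix(ws$x, d[1], d[2] * d[3])
  colnames(m) <- paste0("x", seq_len(ncol(m)))
  m
}

# Target vector for a task from an encoded window set.
window_targets <- function(ws, task, classes = NULL) {
  if (task == "classification") {
    if (is.null(classes)) classes <- dataset_classes(ws$spec)
    factor(ws$class_label, levels = classes)
  } else {
    ws$value
  }
}

#' Train a random-forest baseline
#'
#' Probability forest for classification (per-class scores), regression
#' forest otherwise; both with the configured tree count and depth, run
#' single-threaded with a fixed seed for reproducibility.
#'
#' @param ws an encoded `window_set` (training split)
#' @param cfg an [rf_config()]
#' @return list of class `"pain_model"`
#' @export
train_rf <- function(ws, cfg = rf_config()) {
  x <- flatten_windows(ws)
  classes <- dataset_classes(ws$spec)
  y <- window_targets(ws, cfg$task, classes)
  if (!n_windows(ws)) stop("empty training set", call. = FALSE)
  if (cfg$task == "classification" && length(unique(as.character(y))) < 2L)
    stop("classification training set contains a single class",
         call. = FALSE)
  if (is.factor(y)) y <- droplevels(y) # classes absent from training score 0
  fit <- ranger::ranger(x = x, y = y,
                        num.trees = cfg$n_trees, max.depth = cfg$max_depth,
                        probability = cfg$task == "classification",
                        seed = cfg$seed, num.threads = 1)
  structure(list(kind = "rf", fit = fit, task = cfg$task, config = cfg,
                 classes = classes, n_features = ncol(x)),
            class = "pain_model")
}

#' Prediction container
#'
#' Classification predictions are per-window score vectors (non-negative,
#' summing to 1 over the class set); regression predictions are scalars in
#' `[0, 1]`.
#'
#' @param task "classification" or "regression"
#' @param scores `n x K` score matrix (classification) with class columns
#' @param values numeric vector (regression)
#' @param model_id,modality identifying metadata
#' @return list of class `"prediction_set"`
#' @export
prediction_set <- function(task, scores = NULL, values = NULL,
                           model_id = "model", modality = "eda") {
  if (task == "classification") {
    stopifnot(is.matrix(scores), all(scores >= -1e-9))
    if (nrow(scores))
      stopifnot(max(abs(rowSums(scores) - 1)) < 1e-6)
  } else {
    stopifnot(is.numeric(values))
    if (length(values)) stopifnot(min(values) >= -1e-9, max(values) <= 1 + 1e-9)
  }
  structure(list(task = task, scores = scores, values = values,
                 model_id = model_id, modality = modality),
            class = "prediction_set")
}

#' Number of predictions in a set
#' @param pred a `prediction_set`
#' @return integer
#' @export
n_predictions <- function(pred) {
  if (pred$task == "classification") nrow(pred$scores) else length(pred$values)
}

#' Predicted class index (0-based) of a classification prediction set
#'
#' Ties go to the lowest class index.
#'
#' @param pred a classification `prediction_set`
#' @return integer vector of 0-based class indices
#' @export
predicted_class <- function(pred) {
  stopifnot(pred$task == "classification")
  if (!nrow(pred$scores)) return(integer(0))
  max.col(pred$scores, ties.method = "first") - 1L
}

#' Apply a trained model to a window set
#'
#' @param model a `pain_model` (from [train_rf()] or [train_recurrent()])
#' @param ws a `window_set` with matching window shape
#' @param modality modality tag recorded in the prediction set
#' @return a `prediction_set`
#' @export
predict_windows <- function(model, ws, modality = "eda") {
  stopifnot(inherits(model, "pain_model"))
  if (!n_windows(ws)) {
    return(prediction_set(model$task,
                          scores = matrix(0, 0, length(model$classes),
                                          dimnames = list(NULL, model$classes)),
                          values = numeric(0),
                          model_id = model_id(model), modality = modality))
  }
  if (model$kind == "rf") {
    x <- flatten_windows(ws)
    if (ncol(x) != model$n_features)
      stop("feature dimensionality does not match the trained model",
           call. = FALSE)
    p <- stats::predict(model$fit, data = x, num.threads = 1)$predictions
    if (model$task == "classification") {
      full <- matrix(0, nrow(p), length(model$classes),
                     dimnames = list(NULL, model$classes))
      full[, colnames(p)] <- p
      p <- full
      prediction_set("classification", scores = p,
                     model_id = model_id(model), modality = modality)
    } else {
      prediction_set("regression", values = pmin(pmax(p, 0), 1),
                     model_id = model_id(model), modality = modality)
    }
  } else {
    predict_lstm(model, ws, modality)
  }
}

model_id <- function(model) {
  if (model$kind == "rf")
    paste0("RF", if (model$task == "classification") "c" else "r")
  else model$arch$id
}

#' Trivial majority-vote predictor
#'
#' Always predicts the no-pain class: score 1 on baseline for
#' classification, constant 0 for regression.
#'
#' @param n number of windows
#' @param task "classification" or "regression"
#' @param classes class label vector (classification)
#' @return a `prediction_set`
#' @export
trivial_predictor <- function(n, task = c("classification", "regression"),
                              classes = c("BL", "PH1", "PH2", "PH3")) {
  task <- match.arg(task)
  if (task == "classification") {
    scores <- matrix(0, n, length(classes),
                     dimnames = list(NULL, classes))
    if (n) scores[, "BL"] <- 1
    prediction_set("classification", scores = scores, model_id = "Trivial")
  } else {
    prediction_set("regression", values = rep(0, n), model_id = "Trivial")
  }
}

#' Sample-weighting augmentation indices
#'
#' Fits a random-forest classifier on the facial-activity (FAD) features of
#' the training windows, scores the training set, and duplicates once every
#' window whose score for its own true class exceeds the threshold — i.e.
#' the windows with a clear facial response. Returns the augmented index
#' vector (original order, duplicates appended in order), to be applied to
#' the training windows of either modality.
#'
#' @param fad_ws encoded facial-modality `window_set` of the training split
#' @param threshold score threshold (default 0.3)
#' @param cfg an [rf_config()] for the scoring forest
#' @return integer index vector of length `n + k` with attribute
#'   `"n_duplicated" = k`
#' @export
sample_weighting <- function(fad_ws, threshold = 0.3, cfg = rf_config()) {
  n <- n_windows(fad_ws)
  model <- train_rf(fad_ws, cfg)
  pred <- predict_windows(model, fad_ws, modality = "facial")
  true_score <- pred$scores[cbind(seq_len(n), match(fad_ws$class_label,
                                                    colnames(pred$scores)))]
  dup <- which(true_score > threshold)
  structure(c(seq_len(n), dup), n_duplicated = length(dup))
}

#' Apply an augmentation index vector to a window set
#' @param ws a `window_set`
#' @param idx index vector from [sample_weighting()]
#' @return the augmented `window_set`
#' @export
augment_windows <- function(ws, idx) subset_windows(ws, idx)
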