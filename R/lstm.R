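#' Recurrent architecture specifications
#'
#' Six small sequence models over the 10-step descriptor windows: a single
#' LSTM layer (4 units for A/C, 8 for B/D) with ReLU cell activation whose
#' per-step outputs are flattened and passed through a ReLU dense layer (128
#' neurons for A/C, 64 for B/D) into the output head. Classification heads
#' (`A(c)`/`B(c)`: 7 classes, `C(c)`/`D(c)`: 4 classes) use softmax with
#' categorical cross-entropy; regression heads (`A(r)`/`B(r)` and their
#' 4-class-dataset aliases `C(r)`/`D(r)`) use a single sigmoid unit with
#' binary cross-entropy.
#'
#' @param id architecture id: "A(c)", "B(c)", "C(c)", "D(c)", "A(r)",
#'   "B(r)", "C(r)", "D(r)"
#' @return list of class `"recurrent_arch"` with `units`, `dense_units`,
#'   `output_units`, `task`, `loss`, `output_activation`
#' @export
recurrent_arch <- function(id) {
  valid <- c("A(c)", "B(c)", "C(c)", "D(c)", "A(r)", "B(r)", "C(r)", "D(r)")
  if (!id %in% valid) stop("unknown architecture id: ", id, call. = FALSE)
  letter <- substr(id, 1, 1)
  task <- if (grepl("\\(c\\)", id)) "classification" else "regression"
  big <- letter %in% c("A", "C") # 4 recurrent units, 128 dense
  structure(list(id = id,
                 units = if (big) 4L else 8L,
                 dense_units = if (big) 128L else 64L,
                 output_units = if (task == "regression") 1L
                                else if (letter %in% c("A", "B")) 7L else 4L,
                 task = task,
                 loss = if (task == "classification") "cce" else "bce",
                 output_activation = if (task == "classification") "softmax"
                                     else "sigmoid"),
            class = "recurrent_arch")
}

#' Default architecture for a dataset and task
#'
#' 7-class datasets use the A-shaped models, 4-class datasets the C-shaped
#' ones (both 4 recurrent units, 128 dense neurons), matching the
#' best-performing configuration family.
#'
#' @param spec a [dataset_spec()] or id
#' @param task "classification" or "regression"
#' @return a [recurrent_arch()]
#' @export
default_arch <- function(spec, task = c("classification", "regression")) {
  task <- match.arg(task)
  if (is.character(spec)) spec <- dataset_spec(spec)
  letter <- if (spec$n_classes == 7L) "A" else "C"
  recurrent_arch(paste0(letter, if (task == "classification") "(c)" else "(r)"))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

act_fun <- function(z, act) if (act == "relu") pmax(z, 0) else tanh(z)
# derivative expressed through the activation *output*
act_deriv_from_out <- function(a, act) if (act == "relu") (a > 0) + 0 else 1 - a^2

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

lstm_init <- function(d, arch) {
  h <- arch$units
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1 # forget-gate bias
  t_steps <- 10L
  list(W = glorot(d, 4 * h), U = glorot(h, 4 * h), b = b,
       W1 = glorot(t_steps * h, arch$dense_units),
       b1 = numeric(arch$dense_units),
       W2 = glorot(arch$dense_units, arch$output_units),
       b2 = numeric(arch$output_units))
}

# Forward pass over a batch; X is B x T x d. Returns output plus the caches
# needed for backpropagation through time when keep_cache = TRUE.
lstm_forward <- function(params, X, arch, act = "relu", keep_cache = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; d <- dim(X)[3]
  H <- arch$units
  hs <- matrix(0, B, H); cs <- matrix(0, B, H)
  Hall <- matrix(0, B, T_ * H)
  cache <- if (keep_cache) vector("list", T_) else NULL
  ii <- 1:H; ff <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  oo <- (3 * H + 1):(4 * H)
  for (t in seq_len(T_)) {
    xt <- matrix(X[, t, ], B, d)
    A <- xt %*% params$W + hs %*% params$U +
      matrix(params$b, B, 4 * H, byrow = TRUE)
    gi <- sigmoid(A[, ii, drop = FALSE])
    gf <- sigmoid(A[, ff, drop = FALSE])
    gg_ <- act_fun(A[, gg, drop = FALSE], act)
    go <- sigmoid(A[, oo, drop = FALSE])
    c_prev <- cs
    cs <- gf * c_prev + gi * gg_
    hc <- act_fun(cs, act)
    hs <- go * hc
    Hall[, (t - 1) * H + ii] <- hs
    if (keep_cache)
      cache[[t]] <- list(xt = xt, gi = gi, gf = gf, gg = gg_, go = go,
                         c_prev = c_prev, cs = cs, hc = hc)
  }
  Z1 <- Hall %*% params$W1 + matrix(params$b1, B, length(params$b1),
                                    byrow = TRUE)
  A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% params$W2 + matrix(params$b2, B, length(params$b2),
                                  byrow = TRUE)
  out <- if (arch$output_activation == "softmax") {
    e <- exp(Z2 - apply(Z2, 1, max))
    e / rowSums(e)
  } else {
    sigmoid(Z2)
  }
  list(out = out, Hall = Hall, Z1 = Z1, A1 = A1, cache = cache)
}

lstm_loss <- function(out, Y, arch) {
  eps <- 1e-7
  p <- pmin(pmax(out, eps), 1 - eps)
  if (arch$loss == "cce") -mean(rowSums(Y * log(p)))
  else -mean(Y * log(p) + (1 - Y) * log(1 - p))
}

# Full analytic gradient of the batch loss w.r.t. every parameter.
lstm_backward <- function(params, X, Y, arch, fwd, act = "relu") {
  B <- dim(X)[1]; T_ <- dim(X)[2]; d <- dim(X)[3]
  H <- arch$units
  ii <- 1:H; ff <- (H + 1):(2 * H); oo <- (3 * H + 1):(4 * H)
  dZ2 <- (fwd$out - Y) / B # softmax+CCE and sigmoid+BCE share this form
  dW2 <- crossprod(fwd$A1, dZ2)
  db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$W2)
  dZ1 <- dA1 * (fwd$Z1 > 0)
  dW1 <- crossprod(fwd$Hall, dZ1)
  db1 <- colSums(dZ1)
  dHall <- dZ1 %*% t(params$W1)

  dW <- matrix(0, d, 4 * H); dU <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dh_rec <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    cc <- fwd$cache[[t]]
    dh <- dHall[, (t - 1) * H + ii, drop = FALSE] + dh_rec
    do_ <- dh * cc$hc
    da_o <- do_ * cc$go * (1 - cc$go)
    dc <- dc_next + dh * cc$go * act_deriv_from_out(cc$hc, act)
    di <- dc * cc$gg
    da_i <- di * cc$gi * (1 - cc$gi)
    dg <- dc * cc$gi
    da_g <- dg * act_deriv_from_out(cc$gg, act)
    df <- dc * cc$c_prev
    da_f <- df * cc$gf * (1 - cc$gf)
    dc_next <- dc * cc$gf
    da <- cbind(da_i, da_f, da_g, da_o)
    h_prev <- if (t == 1L) matrix(0, B, H) else
      fwd$cache[[t - 1L]]$go * fwd$cache[[t - 1L]]$hc
    dW <- dW + crossprod(cc$xt, da)
    dU <- dU + crossprod(h_prev, da)
    db <- db + colSums(da)
    dh_rec <- da %*% t(params$U)
  }
  list(W = dW, U = dU, b = db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a recurrent (LSTM) classifier or regressor
#'
#' Mini-batch Adam training of the given architecture on descriptor windows.
#' Classification targets are the 0-based class indices (one-hot encoded
#' internally, categorical cross-entropy); regression targets are the
#' normalized intensities in `[0, 1]` (binary cross-entropy on the sigmoid
#' output). The reference setting trains for 2000 epochs with a learning
#' rate of 1e-4, 1e-5 or 1e-6 and batch size 512; a reduced-epoch profile
#' (fewer epochs, larger learning rate) is appropriate at desk scale.
#'
#' @param ws an encoded `window_set` (training split)
#' @param arch a [recurrent_arch()] (default chosen from the dataset spec)
#' @param lr learning rate
#' @param epochs training epochs
#' @param batch_size mini-batch size
#' @param seed integer seed for initialization and batch shuffling
#' @param activation cell activation, "relu" (default) or "tanh"
#' @param verbose print the epoch loss every 10 epochs
#' @return list of class `"pain_model"`
#' @export
train_recurrent <- function(ws, arch = NULL, lr = 1e-4, epochs = 100L,
                            batch_size = 512L, seed = 1L,
                            activation = "relu", verbose = FALSE) {
  task <- if (!is.null(arch)) arch$task else "regression"
  if (is.null(arch)) arch <- default_arch(ws$spec, task)
  n <- n_windows(ws)
  if (!n) stop("empty training set", call. = FALSE)
  d <- dim(ws$x)[3]
  classes <- if (!is.null(ws$spec)) dataset_classes(ws$spec) else NULL
  if (arch$task == "classification") {
    if (!is.null(ws$spec) && arch$output_units != ws$spec$n_classes)
      stop("architecture output size does not match the dataset class count",
           call. = FALSE)
    Y <- matrix(0, n, arch$output_units)
    Y[cbind(seq_len(n), ws$class_index + 1L)] <- 1
  } else {
    Y <- matrix(ws$value, n, 1)
  }
  set.seed(seed)
  params <- lstm_init(d, arch)
  state <- adam_init(params)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; seen <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, n)]
      Xb <- ws$x[bi, , , drop = FALSE]
      Yb <- Y[bi, , drop = FALSE]
      fwd <- lstm_forward(params, Xb, arch, activation, keep_cache = TRUE)
      grads <- lstm_backward(params, Xb, Yb, arch, fwd, activation)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lstm_loss(fwd$out, Yb, arch) * length(bi)
      seen <- seen + length(bi)
    }
    losses[ep] <- ep_loss / seen
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d: loss %.5f", ep, losses[ep]))
  }
  structure(list(kind = "lstm", params = params, arch = arch,
                 task = arch$task, classes = classes,
                 activation = activation, lr = lr, epochs = epochs,
                 batch_size = batch_size, seed = seed,
                 losses = losses, d = d),
            class = "pain_model")
}

# Prediction for a trained recurrent model, chunked to bound memory.
predict_lstm <- function(model, ws, modality = "eda") {
  n <- n_windows(ws)
  if (dim(ws$x)[3] != model$d)
    stop("feature dimensionality does not match the trained model",
         call. = FALSE)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 4096))
  outs <- lapply(chunks, function(bi) {
    lstm_forward(model$params, ws$x[bi, , , drop = FALSE], model$arch,
                 model$activation)$out
  })
  out <- do.call(rbind, outs)
  if (model$task == "classification") {
    colnames(out) <- model$classes
    prediction_set("classification", scores = out,
                   model_id = model$arch$id, modality = modality)
  } else {
    prediction_set("regression", values = as.numeric(out),
                   model_id = model$arch$id, modality = modality)
  }
}

#' @export
print.pain_model <- function(x, ...) {
  if (x$kind == "rf") {
    cat(sprintf("<pain_model> random forest (%s), %d trees, depth %d\n",
                x$task, x$config$n_trees, x$config$max_depth))
  } else {
    cat(sprintf("<pain_model> %s: LSTM(%d) -> dense(%d) -> %d (%s), lr %g, %d epochs, final loss %.4f\n",
                x$arch$id, x$arch$units, x$arch$dense_units,
                x$arch$output_units, x$arch$loss, x$lr, x$epochs,
                utils::tail(x$losses, 1)))
  }
  invisible(x)
}
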