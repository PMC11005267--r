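## Gradient-based training of the nested / plain LSTM forecasters.
## Full-batch by default; optional seeded mini-batching for large training
## sets. Stops at the epoch cap or when the total squared-error loss falls
## below the configured error threshold.

#' Training configuration
#'
#' Defaults are the package's reference hyperparameters: Adam at 1e-3,
#' hidden width 32, at most 200 epochs, gradient-norm clipping at 5,
#' Gaussian init scale 0.1, zero initial states, stop when the total loss E
#' drops below `error_threshold`.
#'
#' @param epochs maximum passes over the training set (>= 0).
#' @param learning_rate step size (> 0).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param error_threshold stop once total loss E < this value.
#' @param seed integer seed for shuffling (and any parameter init done by
#'   callers that derive seeds from it).
#' @param hidden_size hidden width used by harness-level model builders.
#' @param gradient_clip maximum global gradient norm, or `NULL` to disable.
#' @param batch_size mini-batch size; `NULL` (default) trains full-batch.
#' @param shuffle shuffle window order each epoch (seeded). Only relevant
#'   with mini-batching.
#' @param log_every print a progress line every this many epochs (0 = quiet).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200L, learning_rate = 1e-3,
                         optimizer = c("adam", "sgd"),
                         error_threshold = 1e-4, seed = 1L,
                         hidden_size = 32L, gradient_clip = 5,
                         batch_size = NULL, shuffle = TRUE, log_every = 0L) {
  optimizer <- match.arg(optimizer)
  assert_scalar_num(epochs, "epochs", lower = 0)
  assert_scalar_num(learning_rate, "learning_rate", lower = 0, strict = TRUE)
  assert_scalar_num(error_threshold, "error_threshold", lower = 0)
  assert_scalar_num(hidden_size, "hidden_size", lower = 1)
  if (!is.null(gradient_clip))
    assert_scalar_num(gradient_clip, "gradient_clip", lower = 0, strict = TRUE)
  if (!is.null(batch_size))
    assert_scalar_num(batch_size, "batch_size", lower = 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, error_threshold = error_threshold,
                 seed = as.integer(seed), hidden_size = as.integer(hidden_size),
                 gradient_clip = gradient_clip,
                 batch_size = if (is.null(batch_size)) NULL
                              else as.integer(batch_size),
                 shuffle = isTRUE(shuffle), log_every = as.integer(log_every)),
            class = "train_config")
}

.clip_grads <- function(g, max_norm) {
  if (is.null(max_norm)) return(g)
  nrm <- .grad_global_norm(g)
  if (is.finite(nrm) && nrm > max_norm)
    g <- .map_leaves(function(x) x * (max_norm / nrm), g)
  g
}

#' Train a forecaster on an embedded dataset
#'
#' Iterates forward / backward / parameter update until the epoch cap is
#' reached or the total loss E falls below the configured error threshold.
#' Deterministic given the config seed.
#'
#' @param params initial `nlstm_params` (nested or plain).
#' @param dataset an `embedded_dataset` (or any list with `inputs` and
#'   `targets`).
#' @param config a [train_config()].
#' @return list with `params` (trained), `loss_history` (total E per epoch,
#'   measured on the epoch's pre-update forward passes), `epochs_run`, and
#'   `converged` (TRUE if the error threshold was reached).
#' @export
train <- function(params, dataset, config = train_config()) {
  X <- dataset$inputs; targets <- dataset$targets
  if (is.null(X) || nrow(X) == 0L) stop_ecg("empty dataset")
  n <- nrow(X)
  bs <- min(config$batch_size %||% n, n)
  opt_state <- NULL
  adam_t <- 0L
  loss_history <- numeric(0)
  converged <- FALSE
  if (config$epochs == 0L)
    return(list(params = params, loss_history = loss_history,
                epochs_run = 0L, converged = FALSE))
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- if (config$shuffle && bs < n) sample.int(n) else seq_len(n)
      epoch_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, n)]
        gb <- gradients(params, list(inputs = X[rows, , drop = FALSE],
                                     targets = targets[rows]))
        epoch_loss <- epoch_loss + gb$loss
        g <- .clip_grads(gb$grads, config$gradient_clip)
        if (config$optimizer == "sgd") {
          params <- .map_leaves(function(p, gr) p - config$learning_rate * gr,
                                params, g)
        } else {
          if (is.null(opt_state))
            opt_state <- list(m = .map_leaves(function(x) x * 0, g),
                              v = .map_leaves(function(x) x * 0, g))
          adam_t <- adam_t + 1L
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          opt_state$m <- .map_leaves(function(m, gr) b1 * m + (1 - b1) * gr,
                                     opt_state$m, g)
          opt_state$v <- .map_leaves(function(v, gr) b2 * v + (1 - b2) * gr^2,
                                     opt_state$v, g)
          mhat <- .map_leaves(function(m) m / (1 - b1^adam_t), opt_state$m)
          corr <- 1 - b2^adam_t
          upd <- .map_leaves(function(m, v)
            m / (sqrt(v / corr) + eps), mhat, opt_state$v)
          params <- .map_leaves(function(p, u) p - config$learning_rate * u,
                                params, upd)
        }
        bad <- .find_nonfinite(params)
        if (!is.null(bad))
          stop_ecg("training diverged: non-finite parameter '%s' at epoch %d",
                   bad, epoch)
      }
      if (!is.finite(epoch_loss))
        stop_ecg("training diverged: non-finite loss at epoch %d", epoch)
      loss_history[epoch] <- epoch_loss
      if (config$log_every > 0L && epoch %% config$log_every == 0L)
        message(sprintf("epoch %4d  E = %.6g", epoch, epoch_loss))
      if (epoch_loss < config$error_threshold) { converged <- TRUE; break }
    }
  })
  list(params = params, loss_history = loss_history,
       epochs_run = length(loss_history), converged = converged)
}

#' Root-mean-square error
#' @param predictions,targets numeric vectors of equal length.
#' @return scalar RMSE.
#' @export
rmse <- function(predictions, targets) {
  if (length(predictions) != length(targets)) stop_ecg("length mismatch")
  sqrt(mean((predictions - targets)^2))
}

#' Mean absolute error
#' @param predictions,targets numeric vectors of equal length.
#' @return scalar MAE.
#' @export
mae <- function(predictions, targets) {
  if (length(predictions) != length(targets)) stop_ecg("length mismatch")
  mean(abs(predictions - targets))
}

#' One-step-ahead prediction over a whole series
#'
#' Delay-embeds the series, runs the forecaster on every window, and
#' summarizes tracking error. Residuals are `target - prediction`.
#'
#' @param params trained `nlstm_params`.
#' @param series numeric vector or [ecg_record()].
#' @param config an [embedding_config()].
#' @param model_tag,record_id labels carried into the result.
#' @return a `forecast_result`: list with `predictions`, `targets`,
#'   `residuals`, `rmse`, `mae`, `model_tag`, `record_id`.
#' @export
predict_series <- function(params, series, config = embedding_config(),
                           model_tag = params$kind,
                           record_id = "series") {
  if (inherits(series, "ecg_record")) {
    record_id <- series$record_id
    series <- series$samples
  }
  ds <- embed_series(series, config)
  predict_dataset(params, ds, model_tag = model_tag, record_id = record_id)
}

#' One-step-ahead prediction over an embedded dataset
#'
#' @param params trained `nlstm_params`.
#' @param dataset an `embedded_dataset`.
#' @param model_tag,record_id labels carried into the result.
#' @return a `forecast_result` (see [predict_series()]).
#' @export
predict_dataset <- function(params, dataset, model_tag = params$kind,
                            record_id = "series") {
  y <- .forward_windows(params, dataset$inputs)$y
  res <- dataset$targets - y
  structure(list(predictions = y, targets = dataset$targets,
                 residuals = res,
                 rmse = rmse(y, dataset$targets),
                 mae = mae(y, dataset$targets),
                 model_tag = model_tag, record_id = record_id),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result %s / %s: n=%d  RMSE=%.4g  MAE=%.4g>\n",
              x$record_id, x$model_tag, length(x$predictions),
              x$rmse, x$mae))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' Plain-text JSON checkpoint holding every named weight matrix, the sizes,
#' the cell kind and the output activation (layout version 1).
#'
#' @param params an `nlstm_params`.
#' @param path file path.
#' @return `path` invisibly (save); an `nlstm_params` (load).
#' @export
save_model <- function(params, path) {
  ser <- list(version = 1L, kind = params$kind,
              hidden_size = params$hidden_size,
              input_size = params$input_size,
              output_activation = params$output_activation,
              leaves = lapply(.param_leaves(params), function(x) {
                if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
                else list(dim = NULL, data = as.numeric(x))
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  builder <- if (ser$kind == "nested") nlstm_params else lstm_params
  p <- builder(input_size = ser$input_size, hidden_size = ser$hidden_size,
               seed = 0L, output_activation = ser$output_activation)
  for (nm in names(ser$leaves)) {
    lf <- ser$leaves[[nm]]
    v <- as.numeric(lf$data)
    if (!is.null(lf$dim) && length(lf$dim) == 2L)
      v <- matrix(v, lf$dim[1], lf$dim[2])
    p <- .set_leaf(p, nm, v)
  }
  p
}
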