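## Delay embedding (phase-space reconstruction): turn a scalar series into a
## supervised one-step-ahead regression problem. With window m and delay tau,
## pair j (0-based) has input (x[j], x[j+tau], ..., x[j+(m-1)tau]) and target
## x[j + (m-1)tau + 1], giving exactly n = N - 1 - (m-1)*tau pairs.
## In 1-based prose: samples 1..m predict sample m+1 — for a 5000-sample
## segment with m = 99, tau = 1 that is 4901 input-output pairs.

#' Embedding configuration
#'
#' @param m reconstruction dimension (window length), integer >= 1.
#'   Default 99, so that a 5000-sample segment yields 4901 pairs.
#' @param tau time delay in samples, integer >= 1. Default 1.
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(m = 99L, tau = 1L) {
  assert_scalar_num(m, "m", lower = 1)
  assert_scalar_num(tau, "tau", lower = 1)
  structure(list(m = as.integer(m), tau = as.integer(tau)),
            class = "embedding_config")
}

#' Delay-embed a series into a one-step-ahead training set
#'
#' @param series numeric vector (typically a denoised, normalized ECG
#'   segment).
#' @param config an [embedding_config()].
#' @return an `embedded_dataset`: list with `inputs` (n x m matrix, row j =
#'   delay vector j, time order preserved), `targets` (length-n vector),
#'   `n`, `config`, and `source_indices` (0-based index in `series` of each
#'   target sample).
#' @export
#' @examples
#' d <- embed_series(1:5, embedding_config(m = 3, tau = 1))
#' d$inputs   # rows (1,2,3), (2,3,4)
#' d$targets  # 4 5
embed_series <- function(series, config = embedding_config()) {
  if (inherits(series, "ecg_record")) series <- series$samples
  if (!is.numeric(series)) stop_ecg("invalid field 'series': numeric required")
  m <- config$m; tau <- config$tau
  N <- length(series)
  min_len <- (m - 1L) * tau + 2L
  if (N < min_len)
    stop_ecg("series too short: length %d < minimum %d for m=%d, tau=%d",
             N, min_len, m, tau)
  n <- N - 1L - (m - 1L) * tau
  # column k of the window spans series[(k-1)*tau + (1..n)]
  idx <- outer(seq_len(n), (seq_len(m) - 1L) * tau, `+`)
  inputs <- matrix(series[idx], nrow = n, ncol = m)
  target_pos <- seq_len(n) + (m - 1L) * tau + 1L   # 1-based
  structure(list(inputs = inputs, targets = series[target_pos],
                 n = n, config = config,
                 source_indices = target_pos - 1L),
            class = "embedded_dataset")
}

#' Chronological train/evaluation split
#'
#' Splits the embedded pairs at a time boundary without shuffling. In strict
#' mode (default) evaluation pairs whose input window overlaps the training
#' side's target region are dropped, so no evaluation input contains samples
#' that the training targets covered (leakage guard).
#'
#' @param dataset an `embedded_dataset` from [embed_series()].
#' @param train_fraction fraction of pairs assigned to training (used when
#'   `boundary` is not given).
#' @param boundary explicit pair-count boundary: pairs `1..boundary` train,
#'   the rest evaluate. Must satisfy `0 < boundary < n`.
#' @param strict drop evaluation pairs whose input window crosses the
#'   boundary. Default TRUE.
#' @return list with `train` and `eval`, both `embedded_dataset`s.
#' @export
split_train_eval <- function(dataset, train_fraction = 0.8, boundary = NULL,
                             strict = TRUE) {
  if (!inherits(dataset, "embedded_dataset"))
    stop_ecg("invalid field 'dataset': expected an embedded_dataset")
  n <- dataset$n
  if (is.null(boundary)) {
    assert_scalar_num(train_fraction, "train_fraction", lower = 0, upper = 1,
                      strict = TRUE)
    boundary <- as.integer(floor(n * train_fraction))
  }
  if (boundary < 1L || boundary >= n)
    stop_ecg("degenerate split: boundary %d not in [1, %d)", boundary, n - 1L)
  take <- function(rows) {
    out <- dataset
    out$inputs <- dataset$inputs[rows, , drop = FALSE]
    out$targets <- dataset$targets[rows]
    out$source_indices <- dataset$source_indices[rows]
    out$n <- length(rows)
    out
  }
  train_rows <- seq_len(boundary)
  eval_rows <- (boundary + 1L):n
  if (strict) {
    # pair j (1-based) has input over source samples [j-1, j-1+(m-1)tau] and
    # target at j+(m-1)tau (0-based); the last training target sits at
    # boundary+(m-1)tau, so an eval input must start strictly after it
    span <- (dataset$config$m - 1L) * dataset$config$tau
    eval_rows <- eval_rows[eval_rows - 1L > boundary + span]
  }
  if (length(eval_rows) == 0L)
    stop_ecg("degenerate split: no evaluation pairs survive the leakage guard")
  list(train = take(train_rows), eval = take(eval_rows))
}
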