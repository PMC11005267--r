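## Nested LSTM: an LSTM whose memory-cell update is delegated to a second,
## inner LSTM. Per time step, with element-wise products throughout:
##
##   f_t = sig(Wfx x_t + Wfh h_{t-1} + bf)        forget gate
##   i_t = sig(Wix x_t + Wih h_{t-1} + bi)        input gate
##   g_t = tanh(Wcx x_t + Wch h_{t-1} + bc)       candidate memory
##   o_t = sig(Wox x_t + Woh h_{t-1} + bo)        output gate
##   inner hidden input  hb_{t-1} = f_t * c_{t-1}
##   inner input         xb_t     = i_t * g_t
##   (inner LSTM runs one standard step on (xb_t, hb_{t-1}, cb_{t-1})
##    producing hb_t, cb_t)
##   c_t = hb_t                                   outer memory <- inner hidden
##   h_t = o_t * tanh(c_t)
##
## The plain LSTM baseline shares the gate equations and replaces the inner
## step by c_t = f_t * c_{t-1} + i_t * g_t. Readout: y = act(Wyh h_m), no
## output bias. All state is zero-initialized. Everything here is batched:
## vectors become (hidden x batch) matrices so that full training runs on
## BLAS matrix products rather than R loops.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.gate_block <- function(seedless_rnorm, H, D, scale) {
  list(Wfx = matrix(seedless_rnorm(H * D, scale), H, D),
       Wfh = matrix(seedless_rnorm(H * H, scale), H, H),
       bf  = numeric(H),
       Wix = matrix(seedless_rnorm(H * D, scale), H, D),
       Wih = matrix(seedless_rnorm(H * H, scale), H, H),
       bi  = numeric(H),
       Wcx = matrix(seedless_rnorm(H * D, scale), H, D),
       Wch = matrix(seedless_rnorm(H * H, scale), H, H),
       bc  = numeric(H),
       Wox = matrix(seedless_rnorm(H * D, scale), H, D),
       Woh = matrix(seedless_rnorm(H * H, scale), H, H),
       bo  = numeric(H))
}

#' Initialize Nested LSTM parameters
#'
#' Eight weight matrices and four biases for the outer cell, the same for
#' the inner cell (whose input and hidden sizes both equal the outer hidden
#' size), plus the linear readout row `Wyh`. Weights are Gaussian with the
#' given scale; biases start at zero.
#'
#' @param input_size dimensionality of each time-step input (1 for a scalar
#'   series).
#' @param hidden_size number of hidden units. Default 32.
#' @param seed integer seed for the initial weights.
#' @param init_scale standard deviation of the Gaussian initialization.
#' @param output_activation `"identity"` (linear readout, the default — the
#'   only choice consistent with z-scored targets) or `"sigmoid"` (readout
#'   squashed to (0,1); targets must then be min-max scaled).
#' @return an `nlstm_params` object (`kind = "nested"`).
#' @export
nlstm_params <- function(input_size = 1L, hidden_size = 32L, seed = 1L,
                         init_scale = 0.1,
                         output_activation = c("identity", "sigmoid")) {
  output_activation <- match.arg(output_activation)
  assert_scalar_num(hidden_size, "hidden_size", lower = 1)
  assert_scalar_num(input_size, "input_size", lower = 1)
  H <- as.integer(hidden_size); D <- as.integer(input_size)
  with_seed(seed, {
    rn <- function(n, s) rnorm(n, sd = s)
    p <- list(kind = "nested",
              outer = .gate_block(rn, H, D, init_scale),
              inner = .gate_block(rn, H, H, init_scale),
              Wyh = matrix(rn(H, init_scale), 1L, H),
              hidden_size = H, input_size = D,
              output_activation = output_activation)
  })
  structure(p, class = "nlstm_params")
}

#' Initialize plain LSTM parameters (baseline)
#'
#' @inheritParams nlstm_params
#' @return an `nlstm_params` object with `kind = "plain"` (no inner cell).
#' @export
lstm_params <- function(input_size = 1L, hidden_size = 32L, seed = 1L,
                        init_scale = 0.1,
                        output_activation = c("identity", "sigmoid")) {
  output_activation <- match.arg(output_activation)
  H <- as.integer(hidden_size); D <- as.integer(input_size)
  with_seed(seed, {
    rn <- function(n, s) rnorm(n, sd = s)
    p <- list(kind = "plain",
              outer = .gate_block(rn, H, D, init_scale),
              inner = NULL,
              Wyh = matrix(rn(H, init_scale), 1L, H),
              hidden_size = H, input_size = D,
              output_activation = output_activation)
  })
  structure(p, class = "nlstm_params")
}

#' Zero initial state
#'
#' @param params an `nlstm_params` object.
#' @param batch number of sequences processed in parallel.
#' @return list with matrices `h`, `c` and (nested cell only) `c_inner`,
#'   each `hidden_size x batch`, all zero.
#' @export
nlstm_state <- function(params, batch = 1L) {
  H <- params$hidden_size
  z <- if (batch == 1L) numeric(H) else matrix(0, H, as.integer(batch))
  if (params$kind == "nested") list(h = z, c = z, c_inner = z)
  else list(h = z, c = z)
}

## One batched step. x: (input_size x B); h/c/cb: (H x B).
## Returns all intermediates (needed for backpropagation).
.step_full <- function(params, h, c, cb, x, inner_bypass = FALSE) {
  ou <- params$outer
  f <- .sigmoid(ou$Wfx %*% x + ou$Wfh %*% h + ou$bf)
  i <- .sigmoid(ou$Wix %*% x + ou$Wih %*% h + ou$bi)
  g <- tanh(ou$Wcx %*% x + ou$Wch %*% h + ou$bc)
  o <- .sigmoid(ou$Wox %*% x + ou$Woh %*% h + ou$bo)
  if (params$kind == "plain") {
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    return(list(f = f, i = i, g = g, o = o, c_prev = c, h_prev = h,
                c = c_new, tanh_c = tc, h = o * tc, x = x))
  }
  hb_prev <- f * c        # inner hidden state input
  xb <- i * g             # inner input
  if (inner_bypass) {
    # structural reduction: inner unit replaced by plain accumulation,
    # which collapses the nested cell to the standard LSTM exactly
    c_new <- hb_prev + xb
    tc <- tanh(c_new)
    return(list(f = f, i = i, g = g, o = o, c_prev = c, h_prev = h,
                c = c_new, tanh_c = tc, h = o * tc, x = x))
  }
  iu <- params$inner
  fb <- .sigmoid(iu$Wfx %*% xb + iu$Wfh %*% hb_prev + iu$bf)
  ib <- .sigmoid(iu$Wix %*% xb + iu$Wih %*% hb_prev + iu$bi)
  gb <- tanh(iu$Wcx %*% xb + iu$Wch %*% hb_prev + iu$bc)
  ob <- .sigmoid(iu$Wox %*% xb + iu$Woh %*% hb_prev + iu$bo)
  cb_new <- fb * cb + ib * gb
  tcb <- tanh(cb_new)
  hb <- ob * tcb
  c_new <- hb             # outer memory is the inner hidden output
  tc <- tanh(c_new)
  list(f = f, i = i, g = g, o = o, hb_prev = hb_prev, xb = xb,
       fb = fb, ib = ib, gb = gb, ob = ob,
       cb_prev = cb, cb = cb_new, tanh_cb = tcb,
       c_prev = c, h_prev = h, c = c_new, tanh_c = tc, h = o * tc, x = x)
}

.as_colmat <- function(x, d) {
  if (is.matrix(x)) x else matrix(x, nrow = d)
}

#' One Nested LSTM cell step
#'
#' Applies the full update chain (outer gates, inner LSTM step, memory
#' write-back, output gate) to one input.
#'
#' @param params an `nlstm_params` with `kind = "nested"`.
#' @param state list with `h`, `c`, `c_inner` (vectors of length
#'   `hidden_size`, or `hidden_size x batch` matrices).
#' @param x_t input: length `input_size` vector or `input_size x batch`
#'   matrix.
#' @param inner_bypass if TRUE, replace the inner cell by plain
#'   accumulation `c_t = f_t*c_{t-1} + i_t*g_t`, which reproduces the
#'   standard LSTM exactly.
#' @return updated state (same shapes).
#' @export
nested_cell_step <- function(params, state, x_t, inner_bypass = FALSE) {
  if (params$kind != "nested") stop_ecg("params are not a nested cell")
  H <- params$hidden_size
  x <- .as_colmat(x_t, params$input_size)
  h <- .as_colmat(state$h, H); c <- .as_colmat(state$c, H)
  cb <- .as_colmat(state$c_inner %||% (0 * c), H)
  if (nrow(x) != params$input_size || nrow(h) != H)
    stop_ecg("shape mismatch: x is %dx%d, state h is %dx%d (hidden %d)",
             nrow(x), ncol(x), nrow(h), ncol(h), H)
  s <- .step_full(params, h, c, cb, x, inner_bypass = inner_bypass)
  out <- list(h = s$h, c = s$c,
              c_inner = if (inner_bypass) cb else s$cb)
  if (!is.matrix(state$h)) out <- lapply(out, drop)
  out
}

#' One plain LSTM cell step (baseline)
#'
#' Standard update `c_t = f_t*c_{t-1} + i_t*g_t`, `h_t = o_t*tanh(c_t)`,
#' sharing the gate equations of the nested cell.
#'
#' @param params an `nlstm_params` with `kind = "plain"`.
#' @param state list with `h`, `c`.
#' @param x_t input vector or matrix as in [nested_cell_step()].
#' @return updated state.
#' @export
plain_lstm_step <- function(params, state, x_t) {
  if (params$kind != "plain") stop_ecg("params are not a plain cell")
  H <- params$hidden_size
  x <- .as_colmat(x_t, params$input_size)
  h <- .as_colmat(state$h, H); c <- .as_colmat(state$c, H)
  if (nrow(x) != params$input_size || nrow(h) != H)
    stop_ecg("shape mismatch: x is %dx%d, state h is %dx%d (hidden %d)",
             nrow(x), ncol(x), nrow(h), ncol(h), H)
  s <- .step_full(params, h, c, NULL, x)
  out <- list(h = s$h, c = s$c)
  if (!is.matrix(state$h)) out <- lapply(out, drop)
  out
}

## Stacked view of one gate block: the four input weights become one
## (4H x D) matrix (row blocks f, i, c, o), ditto the hidden weights and
## biases, so each cell step costs two BLAS products instead of eight.
.stack_block <- function(b) {
  list(Wx = rbind(b$Wfx, b$Wix, b$Wcx, b$Wox),
       Wh = rbind(b$Wfh, b$Wih, b$Wch, b$Woh),
       b = c(b$bf, b$bi, b$bc, b$bo))
}

.unstack_block <- function(s, H, D) {
  r <- function(M, k) M[((k - 1) * H + 1):(k * H), , drop = FALSE]
  list(Wfx = r(s$Wx, 1), Wfh = r(s$Wh, 1), bf = s$b[1:H],
       Wix = r(s$Wx, 2), Wih = r(s$Wh, 2), bi = s$b[(H + 1):(2 * H)],
       Wcx = r(s$Wx, 3), Wch = r(s$Wh, 3), bc = s$b[(2 * H + 1):(3 * H)],
       Wox = r(s$Wx, 4), Woh = r(s$Wh, 4), bo = s$b[(3 * H + 1):(4 * H)])
}

## gate activations from a stacked pre-activation matrix (4H x B)
.gates <- function(A, H) {
  i1 <- seq_len(H)
  list(f = .sigmoid(A[i1, , drop = FALSE]),
       i = .sigmoid(A[i1 + H, , drop = FALSE]),
       g = tanh(A[i1 + 2L * H, , drop = FALSE]),
       o = .sigmoid(A[i1 + 3L * H, , drop = FALSE]))
}

## Batched forward over an n x m window matrix (input_size 1): window column
## t is time step t for all n sequences at once. Returns predictions and,
## optionally, the per-step cache for backpropagation.
.forward_windows <- function(params, X, keep_cache = FALSE) {
  n <- nrow(X); m <- ncol(X); H <- params$hidden_size
  if (params$input_size != 1L)
    stop_ecg("windowed forward requires input_size 1 (scalar series)")
  nested <- params$kind == "nested"
  so <- .stack_block(params$outer)
  si <- if (nested) .stack_block(params$inner)
  h <- matrix(0, H, n); c <- h
  cb <- if (nested) h else NULL
  cache <- if (keep_cache) vector("list", m) else NULL
  for (t in seq_len(m)) {
    x <- matrix(X[, t], 1L, n)
    G <- .gates(so$Wx %*% x + so$Wh %*% h + so$b, H)
    if (nested) {
      hb_prev <- G$f * c
      xb <- G$i * G$g
      Gi <- .gates(si$Wx %*% xb + si$Wh %*% hb_prev + si$b, H)
      cb_new <- Gi$f * cb + Gi$i * Gi$g
      tcb <- tanh(cb_new)
      c_new <- Gi$o * tcb
    } else {
      c_new <- G$f * c + G$i * G$g
    }
    tc <- tanh(c_new)
    h_new <- G$o * tc
    if (keep_cache)
      cache[[t]] <- if (nested)
        list(x = x, h_prev = h, c_prev = c, cb_prev = cb,
             f = G$f, i = G$i, g = G$g, o = G$o,
             hb_prev = hb_prev, xb = xb,
             fb = Gi$f, ib = Gi$i, gb = Gi$g, ob = Gi$o,
             tanh_cb = tcb, tanh_c = tc)
      else
        list(x = x, h_prev = h, c_prev = c,
             f = G$f, i = G$i, g = G$g, o = G$o, tanh_c = tc)
    h <- h_new; c <- c_new
    if (nested) cb <- cb_new
  }
  a <- drop(params$Wyh %*% h)
  y <- if (params$output_activation == "sigmoid") .sigmoid(a) else a
  list(y = y, h_final = h, cache = cache)
}

#' One-step-ahead prediction from a single window
#'
#' Feeds the `m` window samples through the cell stepwise from a zero state
#' and applies the readout `y = act(Wyh h_m)`.
#'
#' @param params an `nlstm_params` (nested or plain).
#' @param window numeric vector of `m` samples (model `input_size` must
#'   be 1).
#' @return scalar prediction.
#' @export
forward_sequence <- function(params, window) {
  if (length(window) == 0L) stop_ecg("empty window")
  .forward_windows(params, matrix(as.numeric(window), nrow = 1L))$y
}

#' Squared-error loss
#'
#' Per-step error `E_t = (y_t - that_t)^2 / 2` and total `E = sum(E_t)`.
#'
#' @param predictions numeric vector.
#' @param targets numeric vector, same length.
#' @return list with `E` (scalar) and `E_t` (vector).
#' @export
compute_loss <- function(predictions, targets) {
  if (length(predictions) != length(targets))
    stop_ecg("length mismatch: %d predictions vs %d targets",
             length(predictions), length(targets))
  et <- 0.5 * (predictions - targets)^2
  list(E = sum(et), E_t = et)
}

## Exact gradients of E = sum_j (y_j - target_j)^2/2 w.r.t. every parameter,
## by backpropagation through the unrolled cell. Batched over all windows.
.backward_windows <- function(params, X, targets, fwd) {
  n <- nrow(X); m <- ncol(X); H <- params$hidden_size
  nested <- params$kind == "nested"
  y <- fwd$y; cache <- fwd$cache
  dy <- y - targets
  if (params$output_activation == "sigmoid") dy <- dy * y * (1 - y)
  dy <- matrix(dy, 1L, n)
  gWyh <- dy %*% t(fwd$h_final)
  D <- params$input_size
  so <- .stack_block(params$outer)
  si <- if (nested) .stack_block(params$inner)
  tWh_o <- t(so$Wh); tWx_i <- if (nested) t(si$Wx)
  tWh_i <- if (nested) t(si$Wh)
  gout <- list(Wx = matrix(0, 4 * H, D), Wh = matrix(0, 4 * H, H),
               b = numeric(4 * H))
  ginn <- if (nested) list(Wx = matrix(0, 4 * H, H),
                           Wh = matrix(0, 4 * H, H), b = numeric(4 * H))
  dh <- t(params$Wyh) %*% dy          # H x n, gradient into h_m
  dc_next <- matrix(0, H, n)          # from c_t's use at step t+1
  dcb_next <- if (nested) matrix(0, H, n) else NULL
  for (t in rev(seq_len(m))) {
    s <- cache[[t]]
    do_ <- dh * s$tanh_c
    dc <- dh * s$o * (1 - s$tanh_c^2) + dc_next
    if (nested) {
      dhb <- dc                                   # c_t = hb_t
      dob <- dhb * s$tanh_cb
      dcb <- dhb * s$ob * (1 - s$tanh_cb^2) + dcb_next
      dcb_next <- dcb * s$fb
      dA_i <- rbind((dcb * s$cb_prev) * s$fb * (1 - s$fb),
                    (dcb * s$gb) * s$ib * (1 - s$ib),
                    (dcb * s$ib) * (1 - s$gb^2),
                    dob * s$ob * (1 - s$ob))
      ginn$Wx <- ginn$Wx + dA_i %*% t(s$xb)
      ginn$Wh <- ginn$Wh + dA_i %*% t(s$hb_prev)
      ginn$b <- ginn$b + rowSums(dA_i)
      dxb <- tWx_i %*% dA_i
      dhb_prev <- tWh_i %*% dA_i
      di <- dxb * s$g
      dg <- dxb * s$i
      df <- dhb_prev * s$c_prev
      dc_next <- dhb_prev * s$f
    } else {
      df <- dc * s$c_prev
      di <- dc * s$g
      dg <- dc * s$i
      dc_next <- dc * s$f
    }
    dA <- rbind(df * s$f * (1 - s$f),
                di * s$i * (1 - s$i),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    gout$Wx <- gout$Wx + dA %*% t(s$x)
    gout$Wh <- gout$Wh + dA %*% t(s$h_prev)
    gout$b <- gout$b + rowSums(dA)
    dh <- tWh_o %*% dA
  }
  list(outer = .unstack_block(gout, H, D),
       inner = if (nested) .unstack_block(ginn, H, H),
       Wyh = gWyh)
}

#' Loss gradients for a batch of windows
#'
#' Exact gradients of the total squared-error loss with respect to every
#' parameter, by backpropagation through the unrolled cell. Linear in the
#' batch: duplicating the batch doubles every component.
#'
#' @param params an `nlstm_params` (nested or plain).
#' @param batch list with `inputs` (n x m matrix) and `targets` (length-n
#'   vector), e.g. an `embedded_dataset`.
#' @return list with `grads` (parameter-shaped: `outer`, `inner`, `Wyh`),
#'   `loss` (the total E), `predictions`.
#' @export
gradients <- function(params, batch) {
  X <- batch$inputs; targets <- batch$targets
  if (!is.matrix(X) || length(targets) != nrow(X))
    stop_ecg("batch must carry an n x m 'inputs' matrix and n 'targets'")
  fwd <- .forward_windows(params, X, keep_cache = TRUE)
  g <- .backward_windows(params, X, targets, fwd)
  bad <- .find_nonfinite(g)
  if (!is.null(bad)) stop_ecg("non-finite gradient in parameter '%s'", bad)
  list(grads = g, loss = compute_loss(fwd$y, targets)$E, predictions = fwd$y)
}

## --- parameter-structure utilities ------------------------------------

.param_leaves <- function(p) {
  out <- list()
  if (!is.null(p$outer)) for (nm in names(p$outer))
    out[[paste0("outer.", nm)]] <- p$outer[[nm]]
  if (!is.null(p$inner)) for (nm in names(p$inner))
    out[[paste0("inner.", nm)]] <- p$inner[[nm]]
  out$Wyh <- p$Wyh
  out
}

.set_leaf <- function(p, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2L) p[[parts[1]]][[parts[2]]] <- value
  else p[[name]] <- value
  p
}

.find_nonfinite <- function(g) {
  lv <- .param_leaves(g)
  for (nm in names(lv)) if (any(!is.finite(lv[[nm]]))) return(nm)
  NULL
}

.map_leaves <- function(f, a, b = NULL) {
  la <- .param_leaves(a)
  lb <- if (!is.null(b)) .param_leaves(b)
  out <- a
  for (nm in names(la))
    out <- .set_leaf(out, nm, if (is.null(b)) f(la[[nm]])
                              else f(la[[nm]], lb[[nm]]))
  out
}

.grad_global_norm <- function(g)
  sqrt(sum(vapply(.param_leaves(g), function(x) sum(x^2), numeric(1))))
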