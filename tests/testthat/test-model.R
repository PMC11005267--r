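zero_params <- function(p) ecgforecast:::.map_leaves(function(x) x * 0, p)

test_that("zero parameters force the hidden state chain to zero", {
  for (builder in list(nlstm_params, lstm_params)) {
    p <- zero_params(builder(1, 4, seed = 1))
    st <- nlstm_state(p)
    for (t in 1:6)
      st <- if (p$kind == "nested") nested_cell_step(p, st, rnorm(1))
            else plain_lstm_step(p, st, rnorm(1))
    expect_equal(st$h, rep(0, 4))
    expect_equal(st$c, rep(0, 4))
  }
})

test_that("cells match the naive transliteration oracle to 1e-12", {
  set.seed(20)
  for (rep in 1:10) {
    p <- nlstm_params(1, 2, seed = rep, init_scale = 0.8)
    st <- list(h = rnorm(2), c = rnorm(2), c_inner = rnorm(2))
    x <- rnorm(1)
    got <- nested_cell_step(p, st, x)
    want <- oracle_nested_step(p, st$h, st$c, st$c_inner, x)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$c_inner, want$c_inner, tolerance = 1e-12)

    q <- lstm_params(1, 2, seed = rep + 100, init_scale = 0.8)
    st2 <- list(h = rnorm(2), c = rnorm(2))
    got2 <- plain_lstm_step(q, st2, x)
    want2 <- oracle_plain_step(q, st2$h, st2$c, x)
    expect_equal(got2$h, want2$h, tolerance = 1e-12)
    expect_equal(got2$c, want2$c, tolerance = 1e-12)
  }
})

test_that("bypassing the inner unit reduces the nested cell to plain LSTM", {
  set.seed(21)
  p <- nlstm_params(1, 5, seed = 3, init_scale = 0.6)
  q <- lstm_params(1, 5, seed = 99)
  q$outer <- p$outer; q$Wyh <- p$Wyh     # share the outer gate system
  sn <- nlstm_state(p); sp <- nlstm_state(q)
  for (t in 1:50) {
    x <- rnorm(1)
    sn <- nested_cell_step(p, sn, x, inner_bypass = TRUE)
    sp <- plain_lstm_step(q, sp, x)
    expect_identical(sn$h, sp$h)
    expect_identical(sn$c, sp$c)
  }
})

test_that("scalar hand-trace of the inner update chain", {
  p <- zero_params(nlstm_params(1, 1, seed = 1))
  p$inner$bi <- -50                      # inner input gate ~ 0
  st <- list(h = 0, c = 0, c_inner = 1)
  out <- nested_cell_step(p, st, 0.7)
  # f=i=o=0.5, g=0 -> inner input 0, inner hidden input 0;
  # fb=ob=0.5, ib~0 -> cb = 0.5*1, hb = 0.5*tanh(0.5) = c_t
  expect_equal(out$c_inner, 0.5, tolerance = 1e-12)
  expect_equal(out$c, 0.5 * tanh(0.5), tolerance = 1e-12)
  expect_equal(out$h, 0.5 * tanh(0.5 * tanh(0.5)), tolerance = 1e-12)
})

test_that("readout conventions and determinism", {
  p <- zero_params(nlstm_params(1, 3, seed = 1))
  expect_equal(forward_sequence(p, rnorm(5)), 0)
  ps <- zero_params(nlstm_params(1, 3, seed = 1,
                                 output_activation = "sigmoid"))
  expect_equal(forward_sequence(ps, rnorm(5)), 0.5)
  expect_error(forward_sequence(p, numeric(0)), "empty")

  q <- nlstm_params(1, 6, seed = 8)
  w <- rnorm(10)
  expect_identical(forward_sequence(q, w), forward_sequence(q, w))
})

test_that("loss is the half-squared-error sum", {
  expect_equal(compute_loss(c(1, 2), c(1, 2))$E, 0)
  expect_equal(compute_loss(1, 0)$E, 0.5)
  l <- compute_loss(c(1, 3), c(0, 1))
  expect_equal(l$E, 2.5)
  expect_equal(l$E_t, c(0.5, 2))
  expect_error(compute_loss(1:3, 1:2), "length mismatch")
})

test_that("analytic gradients: linearity, zero residual, finite differences", {
  set.seed(23)
  X <- matrix(rnorm(4 * 5), 4, 5)
  p <- nlstm_params(1, 3, seed = 5, init_scale = 0.4)
  y <- vapply(1:4, function(r) forward_sequence(p, X[r, ]), numeric(1))
  g0 <- gradients(p, list(inputs = X, targets = y))   # zero residual
  expect_equal(ecgforecast:::.grad_global_norm(g0$grads), 0, tolerance = 1e-14)

  targ <- rnorm(4)
  g1 <- gradients(p, list(inputs = X, targets = targ))
  g2 <- gradients(p, list(inputs = rbind(X, X),
                          targets = c(targ, targ)))
  for (nm in names(ecgforecast:::.param_leaves(g1$grads)))
    expect_equal(ecgforecast:::.param_leaves(g2$grads)[[nm]],
                 2 * ecgforecast:::.param_leaves(g1$grads)[[nm]],
                 tolerance = 1e-10)

  for (builder in list(nlstm_params, lstm_params)) {
    p <- builder(1, 3, seed = 17, init_scale = 0.5)
    g <- gradients(p, list(inputs = X, targets = targ))
    fd <- oracle_fd_gradients(p, X, targ)
    for (nm in names(fd))
      expect_lt(max(grad_rel_err(
        ecgforecast:::.param_leaves(g$grads)[[nm]], fd[[nm]])), 1e-4)
  }
})

test_that("training loop contracts: no-op, determinism, loss finiteness", {
  set.seed(30)
  x <- sin((1:300) / 10)
  ds <- embed_series(x, embedding_config(m = 10))
  p <- nlstm_params(1, 4, seed = 2)
  f0 <- train(p, ds, train_config(epochs = 0))
  expect_identical(f0$params, p)
  expect_length(f0$loss_history, 0L)

  tc <- train_config(epochs = 3, learning_rate = 5e-3, seed = 11,
                     batch_size = 64)
  f1 <- train(p, ds, tc)
  f2 <- train(p, ds, tc)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_true(all(is.finite(f1$loss_history)))
  expect_equal(f1$epochs_run, 3L)
  expect_error(train(p, list(inputs = NULL, targets = NULL), tc), "empty")
})

test_that("forecast metrics and result invariants", {
  p <- zero_params(nlstm_params(1, 2, seed = 1))
  fr <- predict_series(p, rep(0, 50), embedding_config(m = 5))
  expect_equal(fr$rmse, 0)
  expect_equal(fr$mae, 0)

  expect_equal(rmse(c(0, 2), c(1, 1)), 1)
  expect_equal(mae(c(0, 2), c(1, 1)), 1)

  set.seed(31)
  for (rep in 1:100) {
    r <- rnorm(sample(2:40, 1))
    expect_gte(rmse(r, 0 * r), mae(r, 0 * r))
  }
})

test_that("checkpoints round-trip through JSON", {
  for (builder in list(nlstm_params, lstm_params)) {
    p <- builder(1, 4, seed = 6)
    path <- withr::local_tempfile(fileext = ".json")
    save_model(p, path)
    q <- load_model(path)
    expect_equal(q$kind, p$kind)
    w <- rnorm(8)
    expect_equal(forward_sequence(q, w), forward_sequence(p, w),
                 tolerance = 1e-12)
  }
})
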