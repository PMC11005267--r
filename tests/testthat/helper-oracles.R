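# Independent oracles: deliberately naive, loop-based implementations used
# only to cross-check the package's vectorized code paths. They share no
# code with R/.

# term-by-term risk vector: R_i = [N - 2i + (N-i) P_i + sum_{k<=i} P_k] / N
oracle_risk_vector <- function(p) {
  n <- length(p)
  r <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(i)) acc <- acc + p[k]
    r[i] <- (n - 2 * i + (n - i) * p[i] + acc) / n
  }
  r
}

# brute-force threshold selection: evaluate the risk at every index and take
# the first minimizer
oracle_select_threshold <- function(detail, finest = detail) {
  sigma <- median(abs(finest)) / 0.6745
  if (sigma == 0) return(list(threshold = 0, sigma = 0, selected_index = NA))
  p <- sort((detail / sigma)^2)
  r <- oracle_risk_vector(p)
  best <- 1L
  for (i in seq_along(r)) if (r[i] < r[best]) best <- i
  list(threshold = sigma * sqrt(p[best]), sigma = sigma, selected_index = best)
}

sigm <- function(z) 1 / (1 + exp(-z))

# straight-line scalar transliteration of the nested cell update chain
oracle_nested_step <- function(p, h_prev, c_prev, cb_prev, x) {
  ou <- p$outer; iu <- p$inner
  f <- sigm(ou$Wfx %*% x + ou$Wfh %*% h_prev + ou$bf)
  i <- sigm(ou$Wix %*% x + ou$Wih %*% h_prev + ou$bi)
  ctil <- tanh(ou$Wcx %*% x + ou$Wch %*% h_prev + ou$bc)
  o <- sigm(ou$Wox %*% x + ou$Woh %*% h_prev + ou$bo)
  hb_prev <- f * c_prev
  xb <- i * ctil
  fb <- sigm(iu$Wfx %*% xb + iu$Wfh %*% hb_prev + iu$bf)
  ib <- sigm(iu$Wix %*% xb + iu$Wih %*% hb_prev + iu$bi)
  cbtil <- tanh(iu$Wcx %*% xb + iu$Wch %*% hb_prev + iu$bc)
  ob <- sigm(iu$Wox %*% xb + iu$Woh %*% hb_prev + iu$bo)
  cb <- fb * cb_prev + ib * cbtil
  hb <- ob * tanh(cb)
  c <- hb
  h <- o * tanh(c)
  list(h = drop(h), c = drop(c), c_inner = drop(cb))
}

# straight-line scalar transliteration of the plain LSTM update
oracle_plain_step <- function(p, h_prev, c_prev, x) {
  ou <- p$outer
  f <- sigm(ou$Wfx %*% x + ou$Wfh %*% h_prev + ou$bf)
  i <- sigm(ou$Wix %*% x + ou$Wih %*% h_prev + ou$bi)
  ctil <- tanh(ou$Wcx %*% x + ou$Wch %*% h_prev + ou$bc)
  o <- sigm(ou$Wox %*% x + ou$Woh %*% h_prev + ou$bo)
  c <- f * c_prev + i * ctil
  h <- o * tanh(c)
  list(h = drop(h), c = drop(c))
}

# loop-based delay embedding with explicit 1-based index arithmetic
oracle_embed <- function(x, m, tau) {
  N <- length(x)
  n <- N - 1 - (m - 1) * tau
  inputs <- matrix(NA_real_, n, m)
  targets <- numeric(n)
  for (j in seq_len(n)) {
    for (k in seq_len(m)) inputs[j, k] <- x[j + (k - 1) * tau]
    targets[j] <- x[j + (m - 1) * tau + 1]
  }
  list(inputs = inputs, targets = targets)
}

# central finite-difference gradient of the total loss for every coordinate
oracle_fd_gradients <- function(params, X, targets, eps = 1e-5) {
  leaves <- ecgforecast:::.param_leaves(params)
  out <- list()
  loss_at <- function(p) {
    y <- vapply(seq_len(nrow(X)),
                function(r) forward_sequence(p, X[r, ]), numeric(1))
    compute_loss(y, targets)$E
  }
  for (nm in names(leaves)) {
    g <- leaves[[nm]]
    g[] <- NA_real_
    for (j in seq_along(leaves[[nm]])) {
      v <- leaves[[nm]]; v[j] <- v[j] + eps
      lp <- loss_at(ecgforecast:::.set_leaf(params, nm, v))
      v <- leaves[[nm]]; v[j] <- v[j] - eps
      lm <- loss_at(ecgforecast:::.set_leaf(params, nm, v))
      g[j] <- (lp - lm) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

# gradient-check comparison with a floor guarding against cancellation
# noise in the finite differences (coordinates with |grad| ~ 1e-8 would
# otherwise compare rounding error against rounding error)
grad_rel_err <- function(analytic, fd) {
  abs(analytic - fd) / pmax(abs(analytic) + abs(fd), 1e-4)
}

# WFDB format-212 writer (test fixture generator; independent of the reader)
write_wfdb_212 <- function(dir, name, signals, fs = 250, gain = 200) {
  nsig <- ncol(signals)
  n <- nrow(signals)
  adc <- round(signals * gain)
  stopifnot(all(abs(adc) < 2048))
  hea <- c(sprintf("%s %d %g %d", name, nsig, fs, n),
           sprintf("%s.dat 212 %g 12 0 0 0 0 ch%d", name, gain,
                   seq_len(nsig) - 1L))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  stream <- as.integer(t(adc))            # interleaved samples
  if (length(stream) %% 2 == 1) stream <- c(stream, 0L)
  s1 <- stream[seq(1, length(stream), by = 2)]
  s2 <- stream[seq(2, length(stream), by = 2)]
  s1u <- ifelse(s1 < 0, s1 + 4096L, s1)
  s2u <- ifelse(s2 < 0, s2 + 4096L, s2)
  b0 <- s1u %% 256L
  b1 <- (s1u %/% 256L) + 16L * (s2u %/% 256L)
  b2 <- s2u %% 256L
  bytes <- as.raw(as.vector(rbind(b0, b1, b2)))
  writeBin(bytes, file.path(dir, paste0(name, ".dat")))
  invisible(file.path(dir, name))
}

# small noisy synthetic fixture shared by denoising tests
make_noisy_fixture <- function(seed = 101, duration = 20) {
  cfg <- synth_config(duration = duration, heart_rate = 72,
                      noise = list(noise_component("baseline_drift", 0.15),
                                   noise_component("powerline", 0.10, 50),
                                   noise_component("white", 0.08)),
                      seed = seed)
  generate_ecg(cfg)
}
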