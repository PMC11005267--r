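test_that("risk vector matches the term-by-term oracle and closed forms", {
  # frozen: oracle_risk_vector(c(1, 4)) computed term-by-term gives
  # R_1 = (2 - 2 + 1*1 + 1)/2 = 1, R_2 = (2 - 4 + 0 + 5)/2 = 1.5
  expect_equal(risk_vector(c(1, 4)), c(1, 1.5))
  expect_equal(which.min(risk_vector(c(1, 4))), 1L)

  expect_equal(risk_vector(0), -1)               # single element closed form

  n <- 13
  expect_equal(risk_vector(rep(0, n)), (n - 2 * seq_len(n)) / n)
  expect_equal(which.min(risk_vector(rep(0, n))), n)

  set.seed(8)
  for (rep in 1:20) {
    p <- sort(rexp(sample(2:60, 1))^2)
    expect_equal(risk_vector(p), oracle_risk_vector(p), tolerance = 1e-12)
  }
  expect_error(risk_vector(c(2, 1)), "sorted")
})

test_that("threshold selection: sigma estimate, degenerate case, recovery", {
  sel <- select_threshold(rnorm(50), finest_details = c(-1, 1, 1, -1))
  expect_equal(sel$sigma, 1 / 0.6745, tolerance = 1e-12)

  z <- select_threshold(c(1, 2, 3), finest_details = rep(0, 8))
  expect_equal(z$threshold, 0)
  expect_equal(z$sigma, 0)

  # MAD/0.6745 is a consistent estimator of a Gaussian sd
  set.seed(42)
  sel2 <- select_threshold(rnorm(4096))
  expect_lt(abs(sel2$sigma - 1), 0.1)
})

test_that("threshold selection equals the brute-force risk minimizer", {
  set.seed(12)
  for (rep in 1:100) {
    n <- sample(5:200, 1)
    detail <- rnorm(n, sd = runif(1, 0.1, 3)) +
      ifelse(runif(n) < 0.1, rnorm(n, sd = 5), 0)   # sparse spikes
    finest <- rnorm(sample(5:200, 1), sd = runif(1, 0.1, 2))
    got <- select_threshold(detail, finest)
    want <- oracle_select_threshold(detail, finest)
    expect_identical(got$selected_index, want$selected_index)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-12)
  }
})

test_that("hard thresholding keeps-or-kills by magnitude", {
  expect_equal(hard_threshold(c(0.5, -0.2, 1.1), 0.6), c(0, 0, 1.1))
  x <- rnorm(40)
  expect_equal(hard_threshold(x, 0), x)
  expect_equal(hard_threshold(c(0.1, -0.3), 0.5), c(0, 0))
  expect_error(hard_threshold(x, -1), "L")

  # retained energy is non-increasing in L
  set.seed(3)
  c0 <- rnorm(200)
  e <- vapply(seq(0, 3, by = 0.1),
              function(L) sum(hard_threshold(c0, L)^2), numeric(1))
  expect_true(all(diff(e) <= 1e-12))
})

test_that("denoising leaves a clean constant signal alone and improves SNR", {
  const <- ecg_record(rep(1.5, 2000), 250)
  out <- denoise(const)
  expect_equal(out$record$samples, const$samples, tolerance = 1e-6)
  # detail coefficients of a constant vanish only to rounding error, so the
  # estimated noise scale (hence threshold) is at most ~1e-15
  expect_true(all(out$thresholds$threshold < 1e-10))

  fix <- make_noisy_fixture(seed = 101)
  dn <- denoise(fix$noisy)
  expect_length(dn$record$samples, length(fix$noisy$samples))
  expect_equal(nrow(dn$thresholds), 7L)
  snr_before <- snr_db(fix$clean, fix$noisy)
  snr_after <- snr_db(fix$clean, dn$record)
  expect_gt(snr_after, snr_before)

  # approximate idempotence: a second pass changes little
  dn2 <- denoise(dn$record)
  expect_lt(rmse(dn2$record$samples, dn$record$samples),
            0.05 * sd(dn$record$samples))
})

test_that("z-score normalization and its inverse", {
  z <- zscore_fit_apply(c(1, 2, 3))
  expect_equal(z$x, c(-1, 0, 1))
  expect_equal(z$stats$mean, 2)
  expect_equal(z$stats$sd, 1)

  set.seed(5); x <- rnorm(500, 7, 3)
  z2 <- zscore_fit_apply(x)
  expect_lt(abs(mean(z2$x)), 1e-10)
  expect_equal(sd(z2$x), 1, tolerance = 1e-12)
  # idempotence on standardized input
  z3 <- zscore_fit_apply(z2$x)
  expect_equal(z3$x, z2$x, tolerance = 1e-10)
  # round trip
  expect_equal(zscore_invert(z2$x, z2$stats), x, tolerance = 1e-10)

  expect_error(zscore_fit_apply(rep(2, 10)), "constant")
  expect_error(zscore_fit_apply(3), "at least 2")
})

test_that("SNR in dB follows the energy-ratio definition", {
  expect_equal(snr_db(c(3, 4), c(3, 5)), 10 * log10(25 / 1))
  x <- rnorm(20)
  expect_identical(snr_db(x, x), Inf)
  expect_equal(snr_db(x, rep(0, 20)), 0)
  expect_error(snr_db(x, rnorm(19)), "length mismatch")
  expect_error(snr_db(rep(0, 5), rnorm(5)), "all-zero reference")
})
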