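test_that("clean generator honours length, determinism and zero cases", {
  cfg <- synth_config(sampling_rate = 250, duration = 20, seed = 4)
  r1 <- generate_clean_ecg(cfg)
  expect_length(r1$samples, 5000L)

  r2 <- generate_clean_ecg(cfg)
  expect_identical(r1$samples, r2$samples)

  # non-integer product rounds
  odd <- synth_config(sampling_rate = 123, duration = 1.7)
  expect_length(generate_clean_ecg(odd)$samples, round(123 * 1.7))

  flat <- synth_config(duration = 2, beat_amplitudes = rep(0, 5))
  expect_true(all(generate_clean_ecg(flat)$samples == 0))
})

test_that("config validation names the offending field", {
  expect_error(synth_config(sampling_rate = -1), "sampling_rate")
  expect_error(synth_config(duration = 0), "duration")
  expect_error(synth_config(heart_rate = 10), "heart_rate")
  expect_error(synth_config(beat_amplitudes = 1:3), "beat_amplitudes")
})

test_that("add_noise contracts: identity, seeds, error cases", {
  rec <- generate_clean_ecg(synth_config(duration = 4))
  expect_identical(add_noise(rec, list(), seed = 1)$noisy$samples,
                   rec$samples)

  spec <- list(noise_component("emg", 0.1))
  a <- add_noise(rec, spec, seed = 1)
  b <- add_noise(rec, spec, seed = 2)
  expect_false(identical(a$noisy$samples, b$noisy$samples))
  # same seed reproduces bit-identically and keeps the clean signal
  a2 <- add_noise(rec, spec, seed = 1)
  expect_identical(a$noisy$samples, a2$noisy$samples)
  expect_identical(a$clean$samples, rec$samples)

  expect_error(noise_component("fancy", 0.1), "unknown noise kind")
  expect_error(add_noise(rec, list(noise_component("powerline", 0.1,
                                                   freq = 200)),
                         seed = 1), "Nyquist")
})

test_that("powerline component carries the analytic sinusoid power", {
  zero <- ecg_record(rep(0, 5000), 250)
  a <- 0.37
  out <- add_noise(zero, list(noise_component("powerline", a, 50)), seed = 9)
  x <- out$noisy$samples
  # total mean power of a sinusoid is a^2/2
  expect_equal(mean(x^2), a^2 / 2, tolerance = 0.01)
  # periodogram peak at 50 Hz
  p <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) * 250 / length(x)
  f <- pmin(f, 250 - f)
  expect_equal(f[which.max(p)], 50, tolerance = 0.1)
})

test_that("every noise kind concentrates >=90% of its power in its band", {
  zero <- ecg_record(rep(0, 5000), 250)
  for (kind in c("baseline_drift", "powerline", "emg", "motion_artifact",
                 "white")) {
    for (seed in c(1, 22)) {
      out <- add_noise(zero, list(noise_component(kind, 0.2, 50)),
                       seed = seed)
      frac <- band_power_fraction(out$noisy$samples, 250,
                                  noise_band(kind, 250, 50))
      expect_gte(frac, 0.90)
    }
  }
})
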