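## Synthetic ECG: quasi-periodic PQRST beats (five Gaussian bumps per beat at
## fixed fractional phase offsets within the RR interval) plus the four
## ambulatory noise classes, all driven by one explicit seed so downstream
## stages are testable with no external recordings.

.pqrst_centers <- c(P = 0.22, Q = 0.37, R = 0.40, S = 0.43, T = 0.63)
.pqrst_widths  <- c(P = 0.035, Q = 0.012, R = 0.016, S = 0.014, T = 0.060)

#' Configuration for the synthetic ECG generator
#'
#' Defaults describe a 20-second single-channel segment sampled at 250 Hz
#' (5000 samples, the segment length used for training throughout the
#' package) with a resting heart rate and conventional PQRST deflection
#' amplitudes in millivolts.
#'
#' @param sampling_rate samples per second (> 0). Default 250.
#' @param duration segment length in seconds (> 0). Default 20.
#' @param heart_rate beats per minute, in (20, 300). Default 75.
#' @param beat_amplitudes named numeric of length 5: peak heights of the
#'   P, Q, R, S, T deflections in mV.
#' @param noise list of noise component specs, each created by
#'   [noise_component()].
#' @param seed integer seed controlling all randomness.
#' @return a `synth_config` list.
#' @export
synth_config <- function(sampling_rate = 250, duration = 20, heart_rate = 75,
                         beat_amplitudes = c(P = 0.15, Q = -0.10, R = 1.00,
                                             S = -0.15, T = 0.30),
                         noise = list(), seed = 1L) {
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 0, strict = TRUE)
  assert_scalar_num(duration, "duration", lower = 0, strict = TRUE)
  assert_scalar_num(heart_rate, "heart_rate", lower = 20, upper = 300,
                    strict = TRUE)
  if (!is.numeric(beat_amplitudes) || length(beat_amplitudes) != 5L ||
      any(!is.finite(beat_amplitudes)))
    stop_ecg("invalid field 'beat_amplitudes': need 5 finite values (P,Q,R,S,T)")
  assert_scalar_num(seed, "seed")
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 heart_rate = heart_rate,
                 beat_amplitudes = stats::setNames(as.numeric(beat_amplitudes),
                                                   names(.pqrst_centers)),
                 noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

#' Describe one noise component
#'
#' The four ambulatory ECG noise classes plus broadband white noise. Bands
#' follow the usual taxonomy: baseline wander has spectral energy
#' concentrated between 0.01 and 1 Hz; powerline interference is a pure 50
#' or 60 Hz sinusoid; electromyographic (EMG) noise is band-limited to
#' 10--500 Hz (clipped at 0.45 x sampling rate); motion artifacts occupy
#' 5--10 Hz.
#'
#' @param kind one of `"baseline_drift"`, `"powerline"`, `"emg"`,
#'   `"motion_artifact"`, `"white"`.
#' @param amplitude for `"powerline"` the sinusoid peak amplitude (mV);
#'   otherwise the target RMS amplitude (mV).
#' @param freq powerline frequency in Hz (50 or 60 typically); ignored for
#'   other kinds.
#' @return a `noise_component` list.
#' @export
noise_component <- function(kind, amplitude, freq = 50) {
  kinds <- c("baseline_drift", "powerline", "emg", "motion_artifact", "white")
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% kinds))
    stop_ecg("unknown noise kind '%s' (expected one of: %s)",
             paste(kind, collapse = ","), paste(kinds, collapse = ", "))
  assert_scalar_num(amplitude, "amplitude", lower = 0)
  assert_scalar_num(freq, "freq", lower = 0, strict = TRUE)
  structure(list(kind = kind, amplitude = amplitude, freq = freq),
            class = "noise_component")
}

#' Declared frequency band of a noise kind
#'
#' Used by the spectral-placement checks: at least 90 percent of a generated
#' component's power should fall inside this band.
#'
#' @param kind noise kind (see [noise_component()]).
#' @param sampling_rate samples per second.
#' @param freq powerline frequency, for `kind = "powerline"`.
#' @return numeric `c(low, high)` in Hz.
#' @export
noise_band <- function(kind, sampling_rate, freq = 50) {
  nyq <- sampling_rate / 2
  switch(kind,
         baseline_drift = c(0.01, 1),
         powerline = c(freq - 1, freq + 1),
         emg = c(10, min(500, 0.45 * sampling_rate)),
         motion_artifact = c(5, min(10, 0.45 * sampling_rate)),
         white = c(0, nyq),
         stop_ecg("unknown noise kind '%s'", kind))
}

## Gaussian noise confined to [lo, hi] Hz by a brickwall FFT mask, scaled to
## unit RMS (caller rescales).
.band_noise <- function(n, rate, lo, hi) {
  z <- rnorm(n)
  Z <- fft(z)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)          # fold: bin k and n-k share |frequency|
  keep <- f >= lo & f <= hi
  keep[1] <- keep[1] && lo <= 0   # DC only if the band includes 0
  Z[!keep] <- 0
  x <- Re(fft(Z, inverse = TRUE)) / n
  s <- sqrt(mean(x^2))
  if (s == 0) x else x / s
}

.gen_noise_component <- function(comp, n, rate) {
  t <- (seq_len(n) - 1) / rate
  a <- comp$amplitude
  switch(comp$kind,
    powerline = {
      if (comp$freq >= rate / 2)
        stop_ecg("powerline frequency %g Hz is at or above Nyquist (%g Hz)",
                 comp$freq, rate / 2)
      a * sin(2 * pi * comp$freq * t + runif(1, 0, 2 * pi))
    },
    baseline_drift = {
      # a few slow sinusoids with random frequencies/phases; energy sits
      # well inside 0.01-1 Hz
      k <- 4L
      fr <- runif(k, 0.05, 0.8)
      ph <- runif(k, 0, 2 * pi)
      w <- runif(k, 0.5, 1)
      x <- drop(sin(outer(t, 2 * pi * fr) + rep(ph, each = n)) %*% w)
      s <- sqrt(mean(x^2))
      if (s == 0) x else a * x / s
    },
    emg = {
      b <- noise_band("emg", rate)
      a * .band_noise(n, rate, b[1], b[2])
    },
    motion_artifact = {
      b <- noise_band("motion_artifact", rate)
      a * .band_noise(n, rate, b[1], b[2])
    },
    white = a * rnorm(n),
    stop_ecg("unknown noise kind '%s'", comp$kind))
}

#' Generate a clean synthetic ECG segment
#'
#' Builds a quasi-periodic signal as the sum of five Gaussian bumps per
#' heartbeat (P, Q, R, S, T) placed at fixed fractional phase offsets within
#' each RR interval. Deterministic: noise components in the config are
#' ignored here (see [add_noise()]).
#'
#' @param config a [synth_config()].
#' @return an [ecg_record()] of exactly
#'   `round(sampling_rate * duration)` samples.
#' @export
#' @examples
#' r <- generate_clean_ecg(synth_config(duration = 2))
#' length(r$samples)  # 500
generate_clean_ecg <- function(config) {
  if (!inherits(config, "synth_config"))
    stop_ecg("invalid field 'config': expected a synth_config object")
  n <- as.integer(round(config$sampling_rate * config$duration))
  t <- (seq_len(n) - 1) / config$sampling_rate
  period <- 60 / config$heart_rate
  phase <- (t / period) %% 1
  x <- numeric(n)
  for (w in names(.pqrst_centers)) {
    d <- phase - .pqrst_centers[[w]]
    d <- d - round(d)               # wrapped distance so beats tile smoothly
    x <- x + config$beat_amplitudes[[w]] *
      exp(-d^2 / (2 * .pqrst_widths[[w]]^2))
  }
  ecg_record(x, config$sampling_rate,
             record_id = sprintf("synth_hr%g_seed%d", config$heart_rate,
                                 config$seed))
}

#' Add seeded noise components to an ECG record
#'
#' Both the clean input and the noisy output are returned so that
#' signal-to-noise ground truth always exists for the denoising stages.
#'
#' @param record an [ecg_record()].
#' @param noise_spec list of [noise_component()] entries (a single component
#'   is also accepted).
#' @param seed integer seed for the component noise draws.
#' @return list with elements `noisy` (ecg_record), `clean` (the input
#'   record) and `components` (named list of numeric noise vectors, names
#'   `kind.1`, `kind.2`, ...).
#' @export
add_noise <- function(record, noise_spec, seed = 1L) {
  if (!inherits(record, "ecg_record"))
    stop_ecg("invalid field 'record': expected an ecg_record")
  if (inherits(noise_spec, "noise_component")) noise_spec <- list(noise_spec)
  if (!is.list(noise_spec))
    stop_ecg("invalid field 'noise_spec': expected a list of noise components")
  n <- length(record$samples)
  comps <- list()
  noisy <- record$samples
  with_seed(seed, {
    for (k in seq_along(noise_spec)) {
      comp <- noise_spec[[k]]
      if (!inherits(comp, "noise_component"))
        comp <- do.call(noise_component, comp)
      v <- .gen_noise_component(comp, n, record$sampling_rate)
      comps[[sprintf("%s.%d", comp$kind, k)]] <- v
      noisy <- noisy + v
    }
  })
  out <- record
  out$samples <- noisy
  list(noisy = out, clean = record, components = comps)
}

#' Generate a synthetic record from a full config (clean + noise)
#'
#' Convenience wrapper: [generate_clean_ecg()] followed by [add_noise()]
#' with the config's noise list and seed.
#'
#' @param config a [synth_config()].
#' @return as [add_noise()]: list with `noisy`, `clean`, `components`.
#' @export
generate_ecg <- function(config) {
  clean <- generate_clean_ecg(config)
  if (length(config$noise) == 0L)
    return(list(noisy = clean, clean = clean, components = list()))
  add_noise(clean, config$noise, seed = config$seed)
}

#' Fraction of signal power inside a frequency band
#'
#' Raw-periodogram band-power ratio, used to verify the spectral placement
#' of generated noise components.
#'
#' @param x numeric signal.
#' @param sampling_rate samples per second.
#' @param band numeric `c(low, high)` in Hz.
#' @return scalar in `[0, 1]`.
#' @export
band_power_fraction <- function(x, sampling_rate, band) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (seq_len(n) - 1) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)
  tot <- sum(p)
  if (tot == 0) return(0)
  sum(p[f >= band[1] & f <= band[2]]) / tot
}
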