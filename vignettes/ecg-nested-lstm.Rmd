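---
title: "One-step-ahead ECG forecasting with Nested LSTM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step-ahead ECG forecasting with Nested LSTM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sudden cardiac death (SCD) is typically preceded by visible degradation of
the electrocardiogram — most prominently the onset of ventricular
fibrillation (VF). A signal-level route to early screening is to learn a
short-horizon forecaster of the ECG itself: a model that predicts sample
$x_{t+1}$ from the preceding $m$ samples tracks the waveform when the
rhythm is stable and its residuals grow when the dynamics change. This
package implements that pipeline end to end for single-channel ECG
segments: wavelet denoising, z-score normalization, delay embedding, a
Nested LSTM forecaster with a plain LSTM baseline, and an experiment
harness that aggregates per-record RMSE/MAE into comparison tables.

Everything runs on synthetic data by default. A WFDB format-212 reader
(`read_wfdb_record()`) is provided for real Holter records, but no external
download is ever required by the tests.

## Denoising model

Ambulatory ECG is contaminated by four classic noise classes: baseline
wander (< 5 Hz, energy concentrated at 0.01–1 Hz), powerline interference
(50/60 Hz), electromyographic noise (broadband, energy mostly 10–500 Hz)
and motion artifacts (energy ~5–10 Hz). `denoise()` applies wavelet
shrinkage:

1. a 7-level db6 discrete wavelet transform with symmetric boundary
   extension (`dwt_decompose()`);
2. a robust noise-scale estimate
   $\hat\sigma = \mathrm{median}(|d_1|)/0.6745$ from the finest detail
   band $d_1$ (the MAD estimate of a Gaussian standard deviation);
3. for each detail level, the threshold minimizing Stein's unbiased risk
   estimate over the sorted squared normalized coefficients
   $P_1 \le \dots \le P_N$:
   $$R_i = \frac{N - 2i + (N - i)P_i + \sum_{k \le i} P_k}{N},
     \qquad L = \hat\sigma\sqrt{P_{i^*}},\quad i^* = \arg\min_i R_i ;$$
4. hard thresholding $d \mapsto d\,\mathbf{1}[|d| \ge L]$ of the detail
   coefficients — the approximation band is never thresholded;
5. the inverse transform.

Design choices worth stating explicitly:

* **Cumulative sum in the risk.** The risk formula's sum term is read as
  $\sum_{k \le i} P_k$, which makes $R_i$ exactly the SURE risk
  $N - 2\,\#\{P_k \le t^2\} + \sum_k \min(P_k, t^2)$ evaluated at
  $t^2 = P_i$ (the classical "rigrsure" rule). A tail-sum or total-sum
  reading would not be an unbiased risk estimate.
* **Magnitude thresholding.** The keep-or-kill condition is applied to
  $|d|$, not to the signed coefficient; signed thresholding would delete
  every negative deflection (Q and S waves).
* **One sigma or per-level sigma.** By default the noise scale is
  estimated once from the finest band and reused at every level
  (`sigma_from = "finest"`); `sigma_from = "per_level"` re-estimates per
  band. The single-scale default matches the usual single-noise-source
  model; the switch exists because the convention is genuinely ambiguous.
* **Degenerate input.** If the finest details are exactly zero (constant
  signal), $\hat\sigma = 0$ and the threshold is defined as 0 — the
  denoiser becomes the identity rather than an error.
* **What this does not remove.** At 250 Hz a 7-level transform puts
  0–~0.5 Hz into the approximation band, which is deliberately left
  untouched, so very slow baseline wander survives denoising. The SNR
  gain on the synthetic fixture comes from the broadband and powerline
  components. This is a property of the stated method, not a bug, and it
  is why the SNR-improvement test asserts direction, not magnitude.

Quality is reported as $\mathrm{SNR} = 10\log_{10}
(\sum x^2 / \sum (\hat x - x)^2)$ dB (`snr_db()`), which requires a clean
reference — hence the synthetic generator always returns the clean signal
alongside the noisy one.

## Normalization and delay embedding

`zscore_fit_apply()` standardizes with the sample (n−1) standard
deviation and keeps $(\bar X, \sigma)$ so errors can be mapped back to
millivolts (RMSE and MAE scale linearly with $\sigma$).

`embed_series()` performs phase-space reconstruction with window $m$ and
delay $\tau$: pair $j$ has input $(x_j, x_{j+\tau}, \dots,
x_{j+(m-1)\tau})$ and target $x_{j+(m-1)\tau+1}$, yielding exactly
$n = N - 1 - (m-1)\tau$ pairs. Defaults $m = 99$, $\tau = 1$: a
5000-sample (20 s at 250 Hz) segment produces 4901 supervised pairs —
in 1-based prose, samples 1–99 predict sample 100, and so on. Indices are
0-based and half-open internally; the 1-based clinical convention appears
only in documentation.

`split_train_eval()` splits chronologically (default 80/20), never
shuffles, and in strict mode drops evaluation pairs whose input window
overlaps the training targets, so no hold-out input contains samples the
model was fitted to predict. Whether published fitting-figure protocols
held data out is typically unstated; both protocols are available
(`eval = "holdout"` vs `eval = "in_sample"` in `experiment_config()`) and
holdout is the default because it is the conservative choice.

## The Nested LSTM cell

A Nested LSTM replaces the additive memory update of a standard LSTM with
a second, inner LSTM. With $\sigma$ the logistic function and $\odot$
element-wise product, the outer cell computes the usual gates

$$f_t = \sigma(W_{fx}x_t + W_{fh}h_{t-1} + b_f), \quad
  i_t = \sigma(W_{ix}x_t + W_{ih}h_{t-1} + b_i),$$
$$\tilde c_t = \tanh(W_{cx}x_t + W_{ch}h_{t-1} + b_c), \quad
  o_t = \sigma(W_{ox}x_t + W_{oh}h_{t-1} + b_o),$$

then hands the inner cell its hidden state and input:

$$\bar h_{t-1} = f_t \odot c_{t-1}, \qquad \bar x_t = i_t \odot \tilde c_t.$$

The inner cell runs one standard LSTM step on
$(\bar x_t, \bar h_{t-1}, \bar c_{t-1})$ producing $\bar h_t, \bar c_t$,
and the outer memory is written back as $c_t = \bar h_t$, followed by
$h_t = o_t \odot \tanh(c_t)$. Setting the inner step to plain accumulation
$c_t = \bar h_{t-1} + \bar x_t$ recovers the standard LSTM exactly — this
structural reduction is tested, and the plain-LSTM baseline shares the
outer gate equations.

The readout is $y = W_{yh} h_m$ with no bias. A sigmoid readout is
available (`output_activation = "sigmoid"`), but the default is linear:
z-scored targets take negative values outside the sigmoid's range, so a
squashed readout is inconsistent with the normalization stage unless
targets are min-max rescaled — a genuine ambiguity in the method as
usually printed; the linear readout is the self-consistent default.

Both cells are implemented from scratch in batched form (state vectors
become hidden × batch matrices; the four gate products collapse into one
stacked matrix product), and gradients are exact backpropagation through
time, validated coordinate-by-coordinate against central finite
differences. The loss is $E = \sum_t \frac{1}{2}(y_t - \hat y_t)^2$; the
½ factor is kept so the textbook gradient identities hold exactly.

## Training

`train_config()` defaults: Adam (learning rate $10^{-3}$), hidden width
32, at most 200 epochs, early stop when $E$ falls below $10^{-4}$,
global gradient-norm clip 5, Gaussian init scale 0.1, zero initial
states, full-batch unless `batch_size` is set. These hyperparameters are
the package's own choices — the method as published reports none, only
wall-clock training time — so they are configuration, never hard-coded.
Determinism: every routine that draws random numbers takes a seed and
restores the caller's RNG state; identical seeds give identical loss
histories and tables.

Because the early-stop threshold applies to the *sum* $E$, its natural
scale grows with the training-set size; the default $10^{-4}$ therefore
acts as "run to the epoch cap" for realistically sized sets, which is the
intended conservative behaviour.

## Synthetic data: what it emulates and what it does not

`generate_clean_ecg()` builds each beat as five Gaussian bumps (P, Q, R,
S, T) at fixed fractional phase offsets (0.22, 0.37, 0.40, 0.43, 0.63 of
the RR interval) with default amplitudes (0.15, −0.10, 1.00, −0.15,
0.30) mV — visually ECG-like, quasi-periodic, differentiable, and exactly
reproducible. Defaults: 250 Hz and 20 s, so one segment is 5000 samples
and the 4901-pair arithmetic of the embedding holds on synthetic data.
`add_noise()` adds seeded components per the noise taxonomy: baseline
drift as a sum of slow sinusoids (0.05–0.8 Hz), powerline as a pure
sinusoid (peak amplitude $a$, mean power $a^2/2$), EMG and motion
artifact as FFT-brickwall band-limited Gaussian noise (10–min(500,
0.45·rate) Hz and 5–10 Hz; the published EMG upper edge of 2 kHz exceeds
Nyquist at 250 Hz and is clipped), and white noise. At least 90 % of each
component's power falls in its declared band, property-tested via the
periodogram.

What the generator does **not** emulate: beat-to-beat morphology and RR
variability, arrhythmic or fibrillatory dynamics, electrode-contact
transients, or multi-lead structure. A green test on synthetic data
establishes that the pipeline's algorithmic contracts hold — not that the
forecaster would achieve any particular accuracy on clinical Holter
recordings, whose error tables depend on non-redistributed data,
unspecified segment offsets and unreported hyperparameters.

Fixture noise amplitudes (0.15 mV drift RMS, 0.10 mV powerline peak,
0.08 mV white RMS against a 1 mV R peak) were chosen once to produce
visibly contaminated but recoverable segments, before any test threshold
was read; they are part of the stated world and are not tuned.

## Experiment harness and scaled-down budgets

`run_experiment()` trains one model per record (never pooled), scores
one-step predictions on the held-out tail, and emits RMSE and MAE tables
with a per-model average footer, in both normalized units and millivolts
(errors de-normalize by the record's fitted $\sigma$). Rerunning with the
same global seed reproduces the tables bit-for-bit.

The acceptance test runs the full 20-record synthetic experiment (both
models) but with a scaled-down training budget — hidden 8, 5 epochs,
mini-batch 256, learning rate 0.01 — so the whole suite fits a single-CPU
time budget. At that budget the Nested LSTM's margin over the plain LSTM
is seed-dependent; the harness therefore *reports* the comparison rather
than asserting superiority.

## Numerical choices

* Wavelet filters: db6 derived by spectral factorization; perfect
  reconstruction verified to relative error below 1e-10 (bound 1e-8).
* Risk minimizer ties broken by the first minimum (`which.min`); ties
  have probability zero for continuous data.
* Gradient checks use central differences with step $10^{-5}$ and
  relative error $|g_a - g_{fd}| / \max(|g_a| + |g_{fd}|, 10^{-4})$; the
  denominator floor prevents coordinates with gradients near $10^{-8}$
  from comparing rounding noise against rounding noise.
* Checkpoints are JSON (text), which costs the last ulp of each double;
  round-trip is validated to 1e-12.
* Non-finite losses, parameters or gradients abort training with the
  offending parameter named, rather than propagating NaN.

## Known limitations

Single-channel only; no multi-step (recursive) forecasting; no SVM / ESN
/ bidirectional-LSTM baselines (the registry accepts additional builders,
but only the two recurrent cells ship); binary WFDB annotation files are
not parsed (pass `event_index` explicitly); the CLI's experiment config is
JSON rather than YAML (no YAML parser in the supported dependency set).
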