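Package: ecgforecast
Title: One-Step-Ahead ECG Forecasting with Nested LSTM Networks
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for early screening of sudden-cardiac-death risk from
    single-channel electrocardiogram (ECG) segments by one-step-ahead signal
    forecasting. Provides wavelet shrinkage denoising with a per-level
    unbiased-risk (SURE) hard threshold on a 7-level db6 decomposition,
    z-score normalization, delay embedding (phase-space reconstruction) of
    the series into a supervised training set, a from-scratch Nested LSTM
    cell (an LSTM whose memory cell is itself an inner LSTM) with exact
    backpropagation-through-time gradients, a plain LSTM baseline, and an
    experiment harness that trains per-record models and aggregates RMSE/MAE
    comparison tables. Includes a seeded synthetic ECG generator (PQRST
    Gaussian-bump morphology plus the standard ambulatory noise classes) so
    the full pipeline is testable without external recordings, and a reader
    for WFDB format-212 Holter records for use with real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
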