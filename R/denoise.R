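## Wavelet shrinkage denoising with a per-level unbiased-risk (SURE,
## "rigrsure"-style) hard threshold:
##   1. estimate the noise scale sigma = median(|finest details|) / 0.6745
##      (the robust MAD estimate of a Gaussian standard deviation);
##   2. per level, sort the squared sigma-normalized detail coefficients
##      into P_1 <= ... <= P_N and evaluate the risk
##        R_i = [ N - 2i + (N - i) P_i + sum_{k<=i} P_k ] / N ;
##   3. the threshold is L = sigma * sqrt(P_{i*}) at the risk minimizer i*;
##   4. detail coefficients with |d| < L are zeroed (hard thresholding,
##      keep-or-kill); approximation coefficients are never touched;
##   5. the inverse transform synthesizes the denoised signal.

#' SURE risk vector over sorted squared coefficients
#'
#' For `P` the ascending-sorted squared (noise-normalized) coefficients of
#' one resolution level, computes
#' `R_i = (N - 2*i + (N - i)*P_i + cumsum(P)_i) / N` for `i = 1..N`. The
#' index minimizing `R` selects the threshold.
#'
#' @param p numeric vector, sorted ascending.
#' @return numeric risk vector of the same length.
#' @export
#' @examples
#' risk_vector(c(1, 4))  # 2.5 1.5
risk_vector <- function(p) {
  n <- length(p)
  if (n < 1L) stop_ecg("risk_vector: empty input")
  if (is.unsorted(p)) stop_ecg("risk_vector: input must be sorted ascending")
  i <- seq_len(n)
  (n - 2 * i + (n - i) * p + cumsum(p)) / n
}

#' Select the unbiased-risk threshold for one level
#'
#' @param detail_coeffs detail coefficients of the level being thresholded.
#' @param finest_details detail coefficients of the finest level, from which
#'   the noise scale `sigma = median(|finest_details|) / 0.6745` is
#'   estimated. Defaults to `detail_coeffs` (per-level noise estimation).
#' @return list with `threshold` (L, on the coefficient scale), `sigma`,
#'   `selected_index` (the risk minimizer i*, 1-based into the sorted
#'   squared coefficients), `risk` (the minimal risk value).
#' @export
select_threshold <- function(detail_coeffs, finest_details = detail_coeffs) {
  if (length(detail_coeffs) == 0L)
    stop_ecg("select_threshold: empty coefficient array")
  sigma <- median(abs(finest_details)) / 0.6745
  if (sigma == 0) {
    # all-zero finest details: degenerate, threshold 0 keeps everything
    return(list(threshold = 0, sigma = 0, selected_index = NA_integer_,
                risk = NA_real_))
  }
  p <- sort((detail_coeffs / sigma)^2)
  r <- risk_vector(p)
  istar <- which.min(r)
  list(threshold = sigma * sqrt(p[istar]), sigma = sigma,
       selected_index = istar, risk = r[istar])
}

#' Hard thresholding (keep-or-kill)
#'
#' Coefficients with magnitude below `L` are zeroed; the rest pass
#' unchanged.
#'
#' @param coeffs numeric coefficients.
#' @param L threshold, >= 0.
#' @return thresholded coefficients.
#' @export
hard_threshold <- function(coeffs, L) {
  assert_scalar_num(L, "L", lower = 0)
  ifelse(abs(coeffs) >= L, coeffs, 0)
}

#' Wavelet denoising of an ECG record
#'
#' Full pipeline: `levels`-deep db6 decomposition, per-level unbiased-risk
#' threshold selection, hard thresholding of the detail coefficients (the
#' approximation band is never thresholded), inverse transform. Output
#' length equals input length.
#'
#' @param record an [ecg_record()].
#' @param levels decomposition depth. Default 7.
#' @param wavelet wavelet name. Default `"db6"`.
#' @param sigma_from `"finest"` (default): one noise-scale estimate from
#'   the level-1 details is used for every level; `"per_level"`: each level
#'   estimates its own scale from its own coefficients.
#' @return list with `record` (denoised [ecg_record()]) and `thresholds`
#'   (a `threshold_set`: data.frame with per-level `level`, `sigma`,
#'   `threshold`, `selected_index`).
#' @export
denoise <- function(record, levels = 7L, wavelet = "db6",
                    sigma_from = c("finest", "per_level")) {
  sigma_from <- match.arg(sigma_from)
  if (!inherits(record, "ecg_record"))
    stop_ecg("invalid field 'record': expected an ecg_record")
  w <- dwt_decompose(record, wavelet_name = wavelet, levels = levels)
  finest <- w$details[[1]]
  rows <- vector("list", levels)
  for (l in seq_len(levels)) {
    ref <- if (sigma_from == "finest") finest else w$details[[l]]
    sel <- select_threshold(w$details[[l]], finest_details = ref)
    w$details[[l]] <- hard_threshold(w$details[[l]], sel$threshold)
    rows[[l]] <- data.frame(level = l, sigma = sel$sigma,
                            threshold = sel$threshold,
                            selected_index = sel$selected_index)
  }
  out <- record
  out$samples <- dwt_reconstruct(w)
  list(record = out,
       thresholds = structure(do.call(rbind, rows),
                              class = c("threshold_set", "data.frame")))
}

#' Z-score normalization with retained statistics
#'
#' Standardizes to mean 0, sample (n-1 divisor) standard deviation 1, and
#' keeps the statistics so predictions can be mapped back to millivolts.
#'
#' @param x numeric vector of length >= 2 with positive spread.
#' @return list with `x` (standardized values) and `stats` (list with
#'   `mean`, `sd`).
#' @export
zscore_fit_apply <- function(x) {
  if (inherits(x, "ecg_record")) x <- x$samples
  if (length(x) < 2L) stop_ecg("zscore: need at least 2 samples")
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop_ecg("zscore: constant input (sd = 0), cannot standardize")
  list(x = (x - m) / s, stats = list(mean = m, sd = s))
}

#' Invert a z-score transform
#'
#' @param x standardized values.
#' @param stats the `stats` element returned by [zscore_fit_apply()].
#' @return values on the original scale.
#' @export
zscore_invert <- function(x, stats) x * stats$sd + stats$mean

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10( sum(reference^2) / sum((estimate - reference)^2) )`.
#' Returns `Inf` when the error energy is exactly zero.
#'
#' @param reference clean reference signal (not all zero).
#' @param estimate signal under evaluation, same length.
#' @return scalar SNR in dB.
#' @export
#' @examples
#' snr_db(c(3, 4), c(3, 5))  # 10*log10(25) ~ 13.98
snr_db <- function(reference, estimate) {
  if (inherits(reference, "ecg_record")) reference <- reference$samples
  if (inherits(estimate, "ecg_record")) estimate <- estimate$samples
  if (length(reference) != length(estimate))
    stop_ecg("length mismatch: %d vs %d", length(reference), length(estimate))
  es <- sum(reference^2)
  if (es == 0) stop_ecg("snr_db: all-zero reference")
  en <- sum((estimate - reference)^2)
  if (en == 0) return(Inf)
  10 * log10(es / en)
}
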