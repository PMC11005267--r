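#' Construct an ECG record
#'
#' The basic container used throughout the package: a single-channel ECG
#' segment in millivolts, its sampling rate, an identifier, and (optionally)
#' the sample index of an annotated event such as ventricular-fibrillation
#' onset.
#'
#' Sample indices are 0-based throughout the package and slices are
#' half-open `[start, end)`; the 1-based convention used in clinical prose
#' is converted at the delay-embedding layer only.
#'
#' @param samples numeric vector of samples (mV); must be finite.
#' @param sampling_rate samples per second; must be > 0.
#' @param record_id identifier string.
#' @param event_index optional 0-based sample index of the annotated event;
#'   must satisfy `0 <= event_index < length(samples)`.
#' @return an object of class `ecg_record` with fields `samples`,
#'   `sampling_rate`, `record_id`, `event_index`.
#' @export
#' @examples
#' r <- ecg_record(sin(seq(0, 2 * pi, length.out = 250)), 250)
#' length(r$samples)
ecg_record <- function(samples, sampling_rate, record_id = "record",
                       event_index = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop_ecg("invalid field 'samples': must be a non-empty numeric vector")
  if (any(!is.finite(samples)))
    stop_ecg("invalid field 'samples': non-finite value at index %d (0-based)",
             which(!is.finite(samples))[1] - 1L)
  assert_scalar_num(sampling_rate, "sampling_rate", lower = 0, strict = TRUE)
  if (!is.null(event_index)) {
    assert_scalar_num(event_index, "event_index", lower = 0,
                      upper = length(samples) - 1L)
    event_index <- as.integer(event_index)
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 record_id = as.character(record_id),
                 event_index = event_index),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.2f s)%s>\n",
              x$record_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate,
              if (is.null(x$event_index)) ""
              else sprintf(", event @ %d", x$event_index)))
  invisible(x)
}

#' @export
length.ecg_record <- function(x) length(x$samples)
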