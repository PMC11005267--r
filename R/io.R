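## CSV and WFDB input/output for single-channel ECG segments.
## CSV layout: one header line `sample_index,mV`, then one row per sample.
## A headerless single numeric column is also accepted on read.

#' Write an ECG record to CSV
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  if (!inherits(record, "ecg_record"))
    stop_ecg("invalid field 'record': expected an ecg_record")
  df <- data.frame(sample_index = seq_along(record$samples) - 1L,
                   mV = record$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ECG record from CSV
#'
#' Accepts either the two-column layout written by [write_csv_record()]
#' (`sample_index,mV`) or a bare single numeric column, with or without a
#' header line. Row order is preserved.
#'
#' @param path file path.
#' @param sampling_rate samples per second of the stored segment.
#' @param record_id identifier; defaults to the file name.
#' @param event_index optional 0-based annotated event index.
#' @return an [ecg_record()].
#' @export
read_csv_record <- function(path, sampling_rate, record_id = basename(path),
                            event_index = NULL) {
  if (!file.exists(path)) stop_ecg("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_ecg("empty file: %s", path)
  first_fields <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first_fields))))
  data_lines <- if (has_header) lines[-1] else lines
  if (length(data_lines) == 0L) stop_ecg("no data rows in %s", path)
  offset <- if (has_header) 1L else 0L
  vals <- vapply(seq_along(data_lines), function(i) {
    fields <- strsplit(data_lines[i], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(fields[length(fields)]))
    if (is.na(v))
      stop_ecg("non-numeric value '%s' at line %d of %s",
               fields[length(fields)], i + offset, path)
    v
  }, numeric(1))
  ecg_record(vals, sampling_rate, record_id = record_id,
             event_index = event_index)
}

#' Read a WFDB format-212 record
#'
#' Minimal reader for the WFDB header/signal pair used by PhysioNet Holter
#' databases: parses `<name>.hea`, decodes the packed 12-bit format-212
#' `.dat` file, and converts the selected channel to physical units (mV)
#' using the per-channel gain and baseline. Binary annotation files are not
#' parsed; supply the annotated event location via `event_index`.
#'
#' @param path record path without extension (e.g. `"data/30"`); `.hea` and
#'   `.dat` must both exist.
#' @param channel 0-based channel to extract. Default 0.
#' @param event_index optional 0-based event sample index.
#' @return an [ecg_record()] with the header's sampling rate.
#' @export
read_wfdb_record <- function(path, channel = 0L, event_index = NULL) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop_ecg("file not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(strsplit(top[3], "/")[[1]][1]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (channel < 0 || channel >= nsig)
    stop_ecg("channel %d out of range (record has %d signals)", channel, nsig)
  sig <- strsplit(trimws(lines[1 + seq_len(nsig)]), "\\s+")
  datfile <- file.path(dirname(path), sig[[1]][1])
  if (!file.exists(datfile)) stop_ecg("file not found: %s", datfile)
  fmt <- sub("x.*$", "", sig[[1]][2])
  if (fmt != "212")
    stop_ecg("unsupported WFDB signal format '%s' (only 212)", fmt)
  # gain field may look like "200(0)/mV"; baseline defaults to 0
  parse_gain <- function(s) {
    gain_part <- strsplit(s, "/")[[1]][1]
    base <- 0
    if (grepl("\\(", gain_part)) {
      base <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_part))
      gain_part <- sub("\\(.*", "", gain_part)
    }
    g <- as.numeric(gain_part)
    if (is.na(g) || g == 0) g <- 200
    c(gain = g, baseline = base)
  }
  gb <- lapply(sig, function(s) if (length(s) >= 3) parse_gain(s[3])
                                else c(gain = 200, baseline = 0))
  raw <- readBin(datfile, "integer", n = file.info(datfile)$size,
                 size = 1L, signed = FALSE)
  ntrip <- length(raw) %/% 3L
  b0 <- raw[3 * seq_len(ntrip) - 2]
  b1 <- raw[3 * seq_len(ntrip) - 1]
  b2 <- raw[3 * seq_len(ntrip)]
  s1 <- b0 + 256L * (b1 %% 16L)          # low byte + low nibble
  s2 <- b2 + 256L * (b1 %/% 16L)         # third byte + high nibble
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  adc <- as.vector(rbind(s1, s2))        # interleaved sample stream
  mat <- matrix(adc[seq_len((length(adc) %/% nsig) * nsig)], nrow = nsig)
  if (!is.na(nsamp) && ncol(mat) > nsamp) mat <- mat[, seq_len(nsamp), drop = FALSE]
  ch <- channel + 1L
  phys <- (mat[ch, ] - gb[[ch]][["baseline"]]) / gb[[ch]][["gain"]]
  ecg_record(phys, fs, record_id = basename(path), event_index = event_index)
}

#' Extract the analysis window around an annotated event
#'
#' Returns the contiguous slice running from `pre_seconds` before the
#' record's annotated event to `post_seconds` after it — e.g. the
#' conventional 20-second screening window of 16 s before and 4 s after a
#' ventricular-fibrillation onset. The slice is half-open in 0-based sample
#' coordinates and has length `round((pre + post) * rate)` exactly; the
#' event index is remapped into slice coordinates.
#'
#' @param record an [ecg_record()] with `event_index` set.
#' @param pre_seconds seconds before the event (>= 0).
#' @param post_seconds seconds after the event (>= 0); `pre + post > 0`.
#' @return an [ecg_record()] slice.
#' @export
#' @examples
#' r <- ecg_record(rnorm(6000), 250, event_index = 4500)
#' w <- extract_event_window(r, 16, 4)
#' length(w$samples)  # 5000
extract_event_window <- function(record, pre_seconds, post_seconds) {
  if (!inherits(record, "ecg_record"))
    stop_ecg("invalid field 'record': expected an ecg_record")
  if (is.null(record$event_index))
    stop_ecg("record '%s' has no event annotation", record$record_id)
  assert_scalar_num(pre_seconds, "pre_seconds", lower = 0)
  assert_scalar_num(post_seconds, "post_seconds", lower = 0)
  rate <- record$sampling_rate
  len <- as.integer(round((pre_seconds + post_seconds) * rate))
  if (len <= 0L) stop_ecg("empty window: pre + post must cover >= 1 sample")
  end <- record$event_index + as.integer(round(post_seconds * rate))  # exclusive
  start <- end - len
  n <- length(record$samples)
  if (start < 0L || end > n)
    stop_ecg("window [%d, %d) exceeds record bounds [0, %d)", start, end, n)
  out <- record
  out$samples <- record$samples[(start + 1L):end]
  out$event_index <- record$event_index - start
  if (out$event_index >= len) out$event_index <- len - 1L
  out$record_id <- sprintf("%s[%d,%d)", record$record_id, start, end)
  out
}
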