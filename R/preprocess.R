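#' Band-pass filter specification
#'
#' A Butterworth band-pass design. The default 3.5--30 Hz passband keeps
#' the theta, alpha and beta rhythms while rejecting slow drifts and line
#' noise; Butterworth designs are used for their maximally flat passband.
#'
#' @param low_cut Lower cutoff, Hz.
#' @param high_cut Upper cutoff, Hz.
#' @param order Filter order per band edge.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 3.5, high_cut = 30, order = 4) {
  if (!(low_cut > 0 && low_cut < high_cut))
    stop("need 0 < low_cut < high_cut")
  if (order < 1) stop("order must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 design = "butterworth"),
            class = "filter_spec")
}

.design_bandpass <- function(spec, rate) {
  nyquist <- rate / 2
  if (spec$high_cut >= nyquist)
    stop("high_cut (", spec$high_cut, " Hz) must be below the Nyquist ",
         "frequency (", nyquist, " Hz)")
  if (spec$low_cut >= nyquist)
    stop("low_cut (", spec$low_cut, " Hz) must be below the Nyquist ",
         "frequency (", nyquist, " Hz)")
  signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / nyquist,
                 type = "pass")
}

#' Apply a Butterworth band-pass filter
#'
#' Causal (forward-only) filtering by default, matching the real-time
#' semantics of an online BCI chain; set `zero_phase = TRUE` for
#' forward-backward filtering when phase distortion matters.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @param zero_phase Use forward-backward (zero-phase) filtering.
#' @return Filtered vector, same length as `samples`.
#' @export
bandpass_butterworth <- function(samples, rate, spec = filter_spec(),
                                 zero_phase = FALSE) {
  stopifnot(is.numeric(samples))
  if (length(samples) <= 3 * spec$order)
    stop("input too short for an order-", spec$order, " filter")
  filt <- .design_bandpass(spec, rate)
  if (zero_phase) signal::filtfilt(filt, samples)
  else as.numeric(signal::filter(filt, samples))
}

#' Analytic frequency response of the band-pass design
#'
#' Evaluates the designed filter's transfer function H(z) = B(z)/A(z)
#' directly at z = exp(i 2 pi f / rate) by polynomial evaluation, giving
#' the magnitude response each probe frequency should see. Serves as the
#' closed-form reference for the filtering routine.
#'
#' @param spec A [filter_spec()].
#' @param rate Sampling rate, Hz.
#' @param freqs Probe frequencies, Hz.
#' @return Numeric vector of magnitude gains (unitless), one per frequency.
#' @export
bandpass_response <- function(spec, rate, freqs) {
  filt <- .design_bandpass(spec, rate)
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / rate * (seq_along(b) - 1))
    num <- sum(b * z)
    z <- exp(-1i * 2 * pi * f / rate * (seq_along(a) - 1))
    den <- sum(a * z)
    Mod(num / den)
  }, numeric(1))
}

#' Square a signal elementwise
#'
#' Rectification by squaring: removes the sign of the oscillation so that
#' subsequent averaging measures power rather than cancelling to zero.
#'
#' @param samples Numeric vector.
#' @return Elementwise square, non-negative.
#' @export
square_signal <- function(samples) {
  stopifnot(is.numeric(samples))
  samples * samples
}

#' Average non-overlapping sample buffers
#'
#' Reduces each consecutive block of `buffer_size` samples to its mean,
#' downsampling the signal to one value per buffer. A trailing partial
#' buffer is dropped rather than padded.
#'
#' @param samples Numeric vector.
#' @param buffer_size Samples per buffer (>= 1).
#' @return Numeric vector of length `floor(length(samples) / buffer_size)`.
#' @export
buffered_average <- function(samples, buffer_size) {
  if (buffer_size < 1) stop("buffer_size must be >= 1")
  buffer_size <- as.integer(buffer_size)
  n_out <- length(samples) %/% buffer_size
  if (n_out == 0L) return(numeric(0))
  colMeans(matrix(samples[seq_len(n_out * buffer_size)], nrow = buffer_size))
}

# Majority label of a character vector; ties resolved toward "interval"
# (an ambiguous buffer is not credited to an object), then alphabetically.
.majority_label <- function(labels) {
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L && "interval" %in% top) "interval" else sort(top)[1]
}

#' Convert a recording into a labeled feature table
#'
#' The preprocessing chain applied per channel: band-pass filter, square,
#' then buffered averaging, so each feature value is the mean band power
#' (uV^2) of one buffer. Each buffer becomes one instance whose class is
#' the majority epoch label inside the buffer (ties go to "interval");
#' `Time` is the 1-based instance index.
#'
#' @param recording An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @param buffer_size Samples per instance buffer.
#' @param zero_phase Passed to [bandpass_butterworth()].
#' @return A feature table: data frame with columns `Time`, one per
#'   channel, and `Class`.
#' @export
to_feature_table <- function(recording, spec = filter_spec(),
                             buffer_size = 32, zero_phase = FALSE) {
  stopifnot(inherits(recording, "eeg_recording"))
  rate <- recording$config$sampling_rate
  n_out <- nrow(recording$samples) %/% as.integer(buffer_size)
  if (n_out == 0L) stop("recording shorter than one buffer")
  feats <- apply(recording$samples, 2, function(col) {
    buffered_average(square_signal(
      bandpass_butterworth(col, rate, spec, zero_phase)), buffer_size)
  })
  feats <- matrix(feats, nrow = n_out,
                  dimnames = list(NULL, colnames(recording$samples)))
  labs <- vapply(seq_len(n_out), function(i) {
    .majority_label(recording$labels[((i - 1) * buffer_size + 1):(i * buffer_size)])
  }, character(1))
  out <- data.frame(Time = seq_len(n_out), feats, Class = labs,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read / write feature-table CSVs
#'
#' The on-disk format is the same for raw recordings and feature tables:
#' a `Time` column, one numeric column per channel, a trailing `Class`
#' column. Reading validates the header and every cell; writing is
#' lossless up to double precision.
#'
#' @param path CSV file path.
#' @return `read_feature_csv`: a validated feature table data frame.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("Time", "Class"))
    if (!col %in% names(df))
      stop("feature CSV is missing the '", col, "' column")
  if (nrow(df) == 0L) stop("feature CSV has no instances")
  df$Class <- as.character(df$Class)
  check_feature_table(df)
  df
}

#' @rdname read_feature_csv
#' @param table A feature table data frame.
#' @export
write_feature_csv <- function(table, path) {
  check_feature_table(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
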