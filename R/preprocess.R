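# Filtering, interval extraction and sample-rate conversion. All public
# time arguments are seconds; intervals are half-open [start, end).

#' Zero-phase Butterworth filtering
#'
#' Applies a Butterworth filter of the given order forward and backward
#' (zero phase, squared magnitude response). The signal is extended at both
#' ends by odd reflection before filtering to suppress edge transients, and
#' trimmed back afterwards, so the output has the input's length. With both
#' cutoffs absent the input is returned unchanged.
#'
#' @param samples numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param highpass high-pass cutoff in Hz, or `NULL`.
#' @param lowpass low-pass cutoff in Hz, or `NULL`.
#' @param order filter order (poles per band edge), default 4.
#' @return numeric vector, same length as `samples`.
#' @section Errors: a cutoff at or above the Nyquist frequency, an inverted
#'   band, or a signal shorter than 3 x order raise validation errors.
#' @export
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 10 * seq_len(fs * 2) / fs)
#' y <- filter_signal(x, fs, highpass = 1, lowpass = 30)
#' max(abs(y - x)) < 0.1
filter_signal <- function(samples, sample_rate, highpass = NULL,
                          lowpass = NULL, order = 4L) {
  stopifnot(is.numeric(samples), is_number(sample_rate), sample_rate > 0,
            is_count(order))
  if (is.null(highpass) && is.null(lowpass)) return(samples)
  nyq <- sample_rate / 2
  for (cut in c(highpass, lowpass)) {
    if (!is_number(cut) || cut <= 0 || cut >= nyq) {
      stop_edfviz("filter cutoff must lie in (0, Nyquist = ", nyq, " Hz)",
                  class = "edfviz_validation_error")
    }
  }
  if (!is.null(highpass) && !is.null(lowpass) && highpass >= lowpass) {
    stop_edfviz("highpass cutoff must be below lowpass cutoff",
                class = "edfviz_validation_error")
  }
  n <- length(samples)
  if (n <= 3L * order) {
    stop_edfviz("signal too short to filter: need more than ", 3L * order,
                " samples", class = "edfviz_length_error")
  }
  bf <- if (is.null(lowpass)) {
    signal::butter(order, highpass / nyq, type = "high")
  } else if (is.null(highpass)) {
    signal::butter(order, lowpass / nyq, type = "low")
  } else {
    signal::butter(order, c(highpass, lowpass) / nyq, type = "pass")
  }
  # odd-reflection padding, then forward and backward passes
  pad <- min(n - 1L, 9L * (2L * order + 1L))
  left <- 2 * samples[1L] - samples[(pad + 1L):2L]
  right <- 2 * samples[n] - samples[(n - 1L):(n - pad)]
  x <- c(left, samples, right)
  y <- signal::filter(bf, x)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Extract a time interval from a recording
#'
#' Restricts every channel and the annotation list to the half-open window
#' `[start_sec, end_sec)`. Annotation onsets are re-expressed relative to
#' the new start; durations are clipped at the new end. The record
#' structure is rebuilt (the original record duration is kept when it
#' divides the new length, otherwise the extract becomes a single record).
#'
#' @param recording an [eeg_recording()].
#' @param start_sec,end_sec interval bounds in seconds,
#'   `0 <= start < end <= duration`.
#' @return An [eeg_recording()] of duration `end_sec - start_sec`.
#' @export
extract_interval <- function(recording, start_sec, end_sec) {
  validate_recording(recording)
  total <- recording_duration(recording)
  if (!is_number(start_sec) || !is_number(end_sec) ||
      start_sec < 0 || start_sec >= end_sec || end_sec > total + 1e-9) {
    stop_edfviz("interval [", start_sec, ", ", end_sec, ") out of range ",
                "[0, ", total, "]", class = "edfviz_bounds_error")
  }
  new_dur <- end_sec - start_sec
  channels <- recording$channels
  for (j in seq_along(channels)) {
    r <- recording$sample_rates[j]
    i0 <- round(start_sec * r)
    i1 <- round(end_sec * r)
    channels[[j]] <- channels[[j]][(i0 + 1L):i1]
  }
  ann <- recording$annotations
  keep <- ann$onset >= start_sec - 1e-9 & ann$onset < end_sec - 1e-9
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann)) {
    ann$onset <- ann$onset - start_sec
    ann$duration <- ifelse(is.na(ann$duration), NA_real_,
                           pmin(ann$duration, new_dur - ann$onset))
  }
  rd <- recording$header$record_duration
  k <- new_dur / rd
  if (abs(k - round(k)) > 1e-9) rd <- new_dur  # fall back to one record
  out <- recording
  out$header$n_records <- as.integer(round(new_dur / rd))
  out$header$record_duration <- rd
  out$header$signal_headers$samples_per_record <-
    as.integer(round(recording$sample_rates * rd))
  out$channels <- channels
  out$annotations <- ann
  validate_recording(out)
  out
}

# continued-fraction rational approximation p/q of x with q <= max_den
rationalize <- function(x, max_den = 1000L, tol = 1e-8) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  if (abs(p1 / q1 - x) > tol) {
    stop_edfviz("rate ratio ", x, " has no small rational form; nearest is ",
                p1, "/", q1, class = "edfviz_validation_error")
  }
  c(p = p1, q = q1)
}

#' Rational (polyphase) resampling
#'
#' Converts a signal between sampling rates whose ratio reduces to a small
#' rational p/q. Each output sample is a windowed-sinc interpolation of the
#' input (Hamming window, anti-aliasing cutoff at the lower of the two
#' Nyquist frequencies); the per-phase filter coefficients are normalised
#' to unit sum, so a constant signal is reproduced exactly, and the input
#' is replicate-padded at the edges. The output has
#' `round(n * to_hz / from_hz)` samples.
#'
#' @param samples numeric vector.
#' @param from_hz,to_hz positive sampling rates; their ratio must be
#'   expressible with denominator at most 1000.
#' @return numeric vector at the new rate.
#' @export
#' @examples
#' length(resample_signal(rep(0, 2560), 256, 200))  # 2000
resample_signal <- function(samples, from_hz, to_hz) {
  stopifnot(is.numeric(samples), is_number(from_hz), from_hz > 0,
            is_number(to_hz), to_hz > 0)
  n <- length(samples)
  m <- as.integer(round(n * to_hz / from_hz))
  if (from_hz == to_hz) return(samples)
  pq <- rationalize(to_hz / from_hz)
  p <- pq[["p"]]; q <- pq[["q"]]
  fc <- min(1, p / q)              # cutoff relative to input Nyquist
  half <- ceiling(8 / fc)          # taps per side, in input samples
  xpad <- c(rep(samples[1L], half + 1L), samples, rep(samples[n], half + q + 1L))
  t_out <- (seq_len(m) - 1L) * q / p          # output times, input units
  i0 <- floor(t_out)
  frac <- t_out - i0
  out <- numeric(m)
  wsum <- numeric(m)
  for (k in -half:half) {
    d <- k - frac                   # tap offset from the output time
    w <- fc * sinc(fc * d) * hamming_taper(d / (half + 1))
    out <- out + w * xpad[i0 + k + half + 2L]
    wsum <- wsum + w
  }
  out / wsum
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hamming_taper <- function(u) {
  ifelse(abs(u) > 1, 0, 0.54 + 0.46 * cos(pi * u))
}
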