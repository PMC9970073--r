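# Time-domain statistics, canonical band power and spectrograms.

# canonical EEG bands, half-open [lo, hi) Hz
EEG_BANDS <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 14),
                  beta = c(14, 30), gamma = c(30, 45))

#' Basic signal statistics
#'
#' Mean, unbiased (n-1) sample variance, and line length — the sum of
#' absolute differences between consecutive samples, a cheap
#' envelope-of-activity feature widely used in seizure detection.
#'
#' @param samples numeric vector of at least 2 samples, physical units.
#' @return list with `mean`, `variance` (units squared) and `line_length`.
#' @export
#' @examples
#' signal_stats(c(1, 2, 3))  # mean 2, variance 1, line length 2
signal_stats <- function(samples) {
  stopifnot(is.numeric(samples))
  if (length(samples) < 2L) {
    stop_edfviz("signal_stats needs at least 2 samples",
                class = "edfviz_length_error")
  }
  list(mean = mean(samples),
       variance = stats::var(samples),
       line_length = sum(abs(diff(samples))))
}

# one-sided periodogram of the mean-removed signal; power normalised so
# that the sum over all bins equals mean((x - mean(x))^2)
periodogram <- function(samples, sample_rate) {
  n <- length(samples)
  x <- samples - mean(samples)
  X <- fft(x)
  nf <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nf)])^2 / n^2
  # double the interior bins (negative-frequency mirror)
  interior <- seq(2L, nf - if (n %% 2L == 0L) 1L else 0L)
  p[interior] <- 2 * p[interior]
  list(freq = (seq_len(nf) - 1L) * sample_rate / n, power = p)
}

#' Power in the canonical EEG frequency bands
#'
#' Computes a one-sided periodogram of the mean-removed signal and sums it
#' over the standard bands delta \[1,4), theta \[4,8), alpha \[8,14), beta
#' \[14,30) and gamma \[30,45) Hz. Band edges are half-open so adjacent
#' bands never double-count a frequency bin.
#'
#' @param samples numeric vector covering at least one second.
#' @param sample_rate sampling rate in Hz. Below 90 Hz the gamma band is
#'   truncated at Nyquist and a warning is issued.
#' @return named numeric vector of band powers (units squared).
#' @export
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 10 * seq_len(2 * fs) / fs)
#' bp <- band_power(x, fs)
#' bp[["alpha"]] / sum(bp)  # ~1: a 10 Hz tone is pure alpha
band_power <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), is_number(sample_rate), sample_rate > 0)
  if (length(samples) < sample_rate) {
    stop_edfviz("band_power needs at least one second of data",
                class = "edfviz_length_error")
  }
  if (sample_rate < 90) {
    warning("sample rate ", sample_rate, " Hz truncates the gamma band at ",
            "Nyquist", call. = FALSE)
  }
  pg <- periodogram(samples, sample_rate)
  vapply(EEG_BANDS, function(b) {
    sum(pg$power[pg$freq >= b[1L] & pg$freq < b[2L]])
  }, numeric(1L))
}

#' Short-time Fourier magnitude spectrogram
#'
#' Hann-windowed STFT magnitude on a linear scale (a display layer may
#' log-scale it). Segment times are segment centers in seconds.
#'
#' @param samples numeric vector, at least one segment long.
#' @param sample_rate sampling rate in Hz.
#' @param segment_sec segment length in seconds (default 1).
#' @param overlap fractional overlap between consecutive segments in
#'   `[0, 1)`, default 0.5.
#' @return list of class `eeg_spectrogram` with `times` (s), `freqs` (Hz,
#'   0 to Nyquist) and `magnitude` (matrix, `length(freqs)` x
#'   `length(times)`).
#' @export
spectrogram <- function(samples, sample_rate, segment_sec = 1, overlap = 0.5) {
  stopifnot(is.numeric(samples), is_number(sample_rate), sample_rate > 0,
            is_number(segment_sec), segment_sec > 0,
            is_number(overlap), overlap >= 0, overlap < 1)
  nseg <- as.integer(round(segment_sec * sample_rate))
  n <- length(samples)
  if (nseg > n) {
    stop_edfviz("segment (", nseg, " samples) longer than signal (", n, ")",
                class = "edfviz_length_error")
  }
  hop <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))
  nf <- floor(nseg / 2) + 1L
  mag <- vapply(starts, function(s) {
    Mod(fft(samples[s:(s + nseg - 1L)] * win))[seq_len(nf)]
  }, numeric(nf))
  structure(
    list(times = (starts - 1L + nseg / 2) / sample_rate,
         freqs = (seq_len(nf) - 1L) * sample_rate / nseg,
         magnitude = matrix(mag, nrow = nf)),
    class = "eeg_spectrogram"
  )
}

#' @export
print.eeg_spectrogram <- function(x, ...) {
  cat("<eeg_spectrogram> ", length(x$freqs), " frequencies x ",
      length(x$times), " segments, 0-", num_str(max(x$freqs)), " Hz\n",
      sep = "")
  invisible(x)
}
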