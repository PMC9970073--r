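# Synthetic 10-20 scalp EEG, clinician-style seizure annotations and
# classifier score streams with known ground truth: the test substrate
# standing in for clinical recordings.

TEN_TWENTY_LABELS <- c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4",
                       "O1", "O2", "F7", "F8", "T3", "T4", "T5", "T6",
                       "FZ", "CZ", "PZ")

# representative oscillation frequency used for each canonical band
BAND_FREQS <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 40)

#' Specification for a synthetic EEG recording
#'
#' Defaults emulate routine 10-20 scalp EEG: 19 channels at 200 Hz,
#' band-structured background activity (one sinusoid per canonical band
#' with a random per-channel phase) plus white Gaussian noise, and an
#' optional high-amplitude 3 Hz spike-wave-like oscillation over the
#' seizure intervals — added on all channels, or on a channel subset to
#' exercise channel-wise predictions.
#'
#' @param n_channels number of channels (default 19; labelled with the
#'   10-20 electrode names, recycled with suffixes beyond 19).
#' @param sample_rate sampling rate in Hz (default 200, the analysis rate;
#'   clinical acquisitions at 256 Hz can be emulated and resampled).
#' @param duration_sec recording length in seconds (default 600).
#' @param band_amplitudes named amplitudes in microvolts for
#'   `delta, theta, alpha, beta, gamma` (defaults 20, 10, 15, 5, 2 — an
#'   awake posterior-dominant pattern).
#' @param noise_sd white-noise standard deviation in microvolts
#'   (default 5).
#' @param seizure_intervals an [interval_set()] of seizure times (seconds),
#'   default none.
#' @param seizure_freq_hz seizure oscillation frequency (default 3 Hz).
#' @param seizure_amp seizure oscillation amplitude in microvolts
#'   (default 100).
#' @param seizure_channels channel labels carrying the seizure (default
#'   all).
#' @param seed integer RNG seed (default 0).
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_channels = 19L, sample_rate = 200,
                       duration_sec = 600,
                       band_amplitudes = c(delta = 20, theta = 10,
                                           alpha = 15, beta = 5, gamma = 2),
                       noise_sd = 5, seizure_intervals = interval_set(),
                       seizure_freq_hz = 3, seizure_amp = 100,
                       seizure_channels = NULL, seed = 0L) {
  stopifnot(is_count(n_channels), is_number(sample_rate), sample_rate > 0,
            is_number(duration_sec), duration_sec > 0,
            all(band_amplitudes >= 0), is_number(noise_sd), noise_sd >= 0,
            inherits(seizure_intervals, "interval_set"),
            is_number(seizure_freq_hz), seizure_freq_hz > 0,
            is_number(seizure_amp), seizure_amp >= 0)
  if (NROW(seizure_intervals) &&
      (any(seizure_intervals[, "start"] < 0) ||
       any(seizure_intervals[, "end"] > duration_sec))) {
    stop_edfviz("seizure intervals must lie within [0, duration)",
                class = "edfviz_validation_error")
  }
  ba <- band_amplitudes[names(BAND_FREQS)]
  if (anyNA(ba)) {
    stop_edfviz("band_amplitudes must name all of: ",
                paste(names(BAND_FREQS), collapse = ", "),
                class = "edfviz_validation_error")
  }
  structure(
    list(n_channels = n_channels, sample_rate = sample_rate,
         duration_sec = duration_sec, band_amplitudes = ba,
         noise_sd = noise_sd, seizure_intervals = seizure_intervals,
         seizure_freq_hz = seizure_freq_hz, seizure_amp = seizure_amp,
         seizure_channels = seizure_channels, seed = as.integer(seed)),
    class = "synth_spec"
  )
}

synth_channel_labels <- function(n) {
  base <- TEN_TWENTY_LABELS
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- sprintf("X%02d", seq_len(n - length(base)))
  c(base, extra)
}

#' Generate a synthetic EEG recording
#'
#' Each channel is the sum of one sinusoid per canonical band (fixed
#' representative frequencies 2, 6, 10, 20 and 40 Hz; independent random
#' phase per channel and band) and white Gaussian noise. Within every
#' seizure interval an additional `seizure_amp` sinusoid at
#' `seizure_freq_hz` is added to the seizure channels, and
#' `"seizure onset"` / `"seizure offset"` annotations are inserted at the
#' interval bounds. Deterministic under the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return An [eeg_recording()].
#' @export
#' @examples
#' rec <- synth_recording(synth_spec(duration_sec = 10, seed = 1))
#' rec
synth_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(round(spec$duration_sec * spec$sample_rate))
  t <- (seq_len(n) - 1L) / spec$sample_rate
  labels <- synth_channel_labels(spec$n_channels)
  sz_ch <- if (is.null(spec$seizure_channels)) labels else spec$seizure_channels
  sz_wave <- numeric(n)
  for (i in seq_len(NROW(spec$seizure_intervals))) {
    iv <- spec$seizure_intervals[i, ]
    inside <- t >= iv[1L] & t < iv[2L]
    sz_wave[inside] <- spec$seizure_amp *
      sin(2 * pi * spec$seizure_freq_hz * t[inside])
  }
  channels <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_channels), function(j) {
      x <- numeric(n)
      for (b in names(BAND_FREQS)) {
        phase <- runif(1L, 0, 2 * pi)
        x <- x + spec$band_amplitudes[[b]] *
          sin(2 * pi * BAND_FREQS[[b]] * t + phase)
      }
      if (spec$noise_sd > 0) x <- x + rnorm(n, 0, spec$noise_sd)
      if (labels[j] %in% sz_ch) x <- x + sz_wave
      x
    })
  })
  names(channels) <- labels
  ann <- NULL
  if (NROW(spec$seizure_intervals)) {
    ann <- data.frame(
      onset = as.vector(rbind(spec$seizure_intervals[, "start"],
                              spec$seizure_intervals[, "end"])),
      duration = NA_real_,
      text = rep(c("seizure onset", "seizure offset"),
                 NROW(spec$seizure_intervals)),
      stringsAsFactors = FALSE
    )
    # an offset exactly at the end of the record is a valid instant
    ann$onset <- pmin(ann$onset, spec$duration_sec)
  }
  amp_bound <- sum(spec$band_amplitudes) + spec$seizure_amp +
    6 * spec$noise_sd
  eeg_recording(channels, sample_rate = spec$sample_rate, annotations = ann,
                physical_range = c(-1, 1) * ceiling(amp_bound),
                patient_field = sprintf("SYN%03d X X synthetic", spec$seed),
                recording_field = "Startdate 01-JAN-2001 X X synthetic")
}

#' Window labels for seizure intervals
#'
#' A window is labelled 1 exactly when its half-open span
#' `[i * window_sec, (i+1) * window_sec)` intersects any seizure interval.
#'
#' @param seizure_intervals an [interval_set()].
#' @param duration_sec total duration covered by the windows.
#' @param window_sec window length in seconds (default 1).
#' @return integer 0/1 vector of length `duration_sec / window_sec`.
#' @export
window_labels <- function(seizure_intervals, duration_sec, window_sec = 1) {
  stopifnot(inherits(seizure_intervals, "interval_set"))
  m <- as.integer(round(duration_sec / window_sec))
  starts <- (seq_len(m) - 1L) * window_sec
  lab <- integer(m)
  for (i in seq_len(NROW(seizure_intervals))) {
    iv <- seizure_intervals[i, ]
    lab[starts < iv[2L] & (starts + window_sec) > iv[1L]] <- 1L
  }
  lab
}

#' Generate synthetic classifier scores of controllable quality
#'
#' Emulates a window-wise seizure detector: per window,
#' `score = clip(label + Normal(0, quality_sd), 0, 1)` where `label` is
#' the seizure-overlap indicator. `quality_sd = 0` gives a perfect
#' detector; large values drown the signal in noise.
#'
#' @param labels integer 0/1 window labels (e.g. from [window_labels()]).
#' @param quality_sd score noise standard deviation, >= 0.
#' @param window_sec seconds per window (default 1; carried through as
#'   metadata).
#' @param seed integer RNG seed.
#' @return list with `scores`, `labels` and `window_sec`.
#' @export
#' @examples
#' lab <- window_labels(interval_set(10, 20), 60)
#' s <- synth_scores(lab, quality_sd = 0.1, seed = 1)
#' range(s$scores)
synth_scores <- function(labels, quality_sd, window_sec = 1, seed = 0L) {
  stopifnot(all(labels %in% c(0, 1)), is_number(quality_sd), quality_sd >= 0)
  scores <- with_seed(as.integer(seed), {
    pmin(pmax(labels + rnorm(length(labels), 0, quality_sd), 0), 1)
  })
  list(scores = scores, labels = as.integer(labels), window_sec = window_sec)
}
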