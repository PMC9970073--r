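# Shared fixtures: everything is generated in code at test time.

# small multichannel recording with annotations, deterministic
make_test_recording <- function(duration = 10, sample_rate = 200,
                                labels = c("FP1", "F7", "C3", "C4", "CZ"),
                                seed = 1) {
  n <- duration * sample_rate
  t <- (seq_len(n) - 1) / sample_rate
  channels <- withr::with_seed(seed, {
    stats::setNames(lapply(seq_along(labels), function(j) {
      10 * sin(2 * pi * (5 + j) * t) + rnorm(n, 0, 2)
    }), labels)
  })
  eeg_recording(
    channels, sample_rate = sample_rate,
    annotations = data.frame(
      onset = round(c(0.2, 0.55) * duration, 3),
      duration = c(NA, round(0.2 * duration, 3)),
      text = c("eyes closed", "seizure onset")),
    physical_range = c(-100, 100)
  )
}

# independent byte-level EDF encoder used as the read_edf oracle: writes a
# 1-channel, 1-record file directly from the published byte layout
write_reference_edf <- function(path, digital, phys_min = -1000,
                                phys_max = 1000, dig_min = -32768L,
                                dig_max = 32767L, record_duration = 1) {
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) formatC(as.character(s), width = -w)
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("test patient", 80), con, eos = NULL)
  writeChar(pad("test recording", 80), con, eos = NULL)
  writeChar(pad("02.03.04", 8), con, eos = NULL)
  writeChar(pad("10.20.30", 8), con, eos = NULL)
  writeChar(pad(256 + 256, 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(1, 8), con, eos = NULL)
  writeChar(pad(record_duration, 8), con, eos = NULL)
  writeChar(pad(1, 4), con, eos = NULL)
  writeChar(pad("TESTCH", 16), con, eos = NULL)
  writeChar(pad("", 80), con, eos = NULL)
  writeChar(pad("uV", 8), con, eos = NULL)
  writeChar(pad(phys_min, 8), con, eos = NULL)
  writeChar(pad(phys_max, 8), con, eos = NULL)
  writeChar(pad(dig_min, 8), con, eos = NULL)
  writeChar(pad(dig_max, 8), con, eos = NULL)
  writeChar(pad("", 80), con, eos = NULL)
  writeChar(pad(length(digital), 8), con, eos = NULL)
  writeChar(pad("", 32), con, eos = NULL)
  writeBin(as.integer(digital), con, size = 2L, endian = "little")
  invisible(path)
}

random_annotations <- function(n, total) {
  onset <- round(sort(runif(n, 0, total - 1)), 3)
  duration <- ifelse(runif(n) < 0.5, NA_real_,
                     round(runif(n, 0, pmin(1, total - onset)), 3))
  data.frame(onset = onset, duration = duration,
             text = paste0("note ", seq_len(n)), stringsAsFactors = FALSE)
}
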