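# EDF/EDF+C codec: byte-level decoding against an independent encoder,
# write/read round trips, TAL grammar, de-identification, and prediction
# channel storage.

test_that("read_edf decodes 16-bit samples with the standard linear scaling", {
  f <- withr::local_tempfile(fileext = ".edf")
  digital <- c(-32768L, -5L:4L, 0L, 32767L)
  write_reference_edf(f, digital)
  rec <- read_edf(f)

  expected <- (digital + 32768) * 2000 / 65535 - 1000
  expect_equal(rec$channels[["TESTCH"]], expected, tolerance = 1e-9)
  # digital 0 on this range sits just above zero physical
  expect_equal(expected[digital == 0L], rep(0.015259, 2), tolerance = 1e-4)
  expect_equal(rec$header$patient_field, "test patient")
  expect_equal(rec$header$start_date, as.Date("2004-03-02"))
  expect_equal(rec$header$start_time, "10.20.30")
  expect_equal(rec$sample_rates, length(digital))
  expect_equal(nrow(rec$annotations), 0L)
})

test_that("malformed headers and discontinuous files are rejected naming the offending field", {
  f <- withr::local_tempfile(fileext = ".edf")
  write_reference_edf(f, 1:10)
  raw <- readBin(f, "raw", file.info(f)$size)

  bad <- raw
  bad[237:244] <- charToRaw("abc     ")  # n_records field
  f2 <- withr::local_tempfile(fileext = ".edf")
  writeBin(bad, f2)
  expect_error(read_edf(f2), "number of records", class = "edfviz_format_error")

  bad <- raw
  bad[193:197] <- charToRaw("EDF+D")
  writeBin(bad, f2)
  expect_error(read_edf(f2), class = "edfviz_unsupported_error")

  expect_error(read_edf(tempfile()), class = "edfviz_io_error")
})

test_that("write/read round trip preserves header, samples and annotations", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      nch <- sample(1:4, 1)
      rate <- sample(c(100, 200, 256), 1)
      dur <- sample(3:6, 1)
      channels <- stats::setNames(
        lapply(seq_len(nch), function(j) runif(rate * dur, -90, 90)),
        paste0("CH", seq_len(nch))
      )
      rec <- eeg_recording(channels, sample_rate = rate,
                           annotations = random_annotations(4, dur),
                           physical_range = c(-100, 100),
                           patient_field = "P X X X")
      f <- withr::local_tempfile(fileext = ".edf")
      write_edf(rec, f)
      back <- read_edf(f)

      expect_equal(back$header$n_records, rec$header$n_records)
      expect_equal(back$header$record_duration, rec$header$record_duration)
      expect_equal(back$header$patient_field, rec$header$patient_field)
      expect_equal(back$header$start_date, rec$header$start_date)
      expect_equal(back$header$signal_headers$label,
                   rec$header$signal_headers$label)
      expect_equal(back$header$signal_headers$samples_per_record,
                   rec$header$signal_headers$samples_per_record)
      step <- 200 / 65535
      for (j in seq_len(nch)) {
        expect_lt(max(abs(back$channels[[j]] - rec$channels[[j]])), step)
      }
      # TAL codec is exact: onsets carry <= 3 decimals by construction
      expect_equal(back$annotations, rec$annotations)
    })
  }
})

test_that("annotations are serialised with the TAL byte grammar", {
  rec <- eeg_recording(list(C3 = numeric(2000)), sample_rate = 200,
                       annotations = data.frame(onset = 5.5, duration = 2,
                                                text = "seizure onset"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  bytes <- readBin(f, "raw", file.info(f)$size)
  tal <- c(charToRaw("+5.5"), as.raw(0x15), charToRaw("2"), as.raw(0x14),
           charToRaw("seizure onset"), as.raw(0x14), as.raw(0))
  hay <- paste(as.character(bytes), collapse = " ")
  expect_true(grepl(paste(as.character(tal), collapse = " "), hay,
                    fixed = TRUE))
})

test_that("file size follows the header arithmetic exactly", {
  rec <- synth_recording(synth_spec(duration_sec = 60, seed = 3))
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  # 19 signals + 1 annotation signal; annotation channel needs 8 int16
  # slots per record (timekeeping TAL only)
  expect_identical(file.info(f)$size,
                   256 + 20 * 256 + 60 * (19 * 200 * 2 + 8 * 2))
})

test_that("out-of-range samples are clipped on write with a warning", {
  rec <- eeg_recording(list(A = c(numeric(99), 500)), sample_rate = 100,
                       physical_range = c(-100, 100))
  f <- withr::local_tempfile(fileext = ".edf")
  expect_warning(write_edf(rec, f), "clipped")
  expect_equal(max(read_edf(f)$channels[["A"]]), 100, tolerance = 1e-9)
})

test_that("anonymize_edf applies sentinel defaults, honours overrides, and is idempotent", {
  rec <- make_test_recording()
  rec$header$patient_field <- "John Doe M 01-JAN-1980"
  rec$header$recording_field <- "Startdate 05-JUN-2019 EMU"
  rec$header$start_date <- as.Date("2019-06-05")
  rec$header$start_time <- "13.45.00"

  anon <- anonymize_edf(rec)
  expect_identical(anon$header$patient_field, "X X X X")
  expect_identical(anon$header$recording_field, "Startdate X X X X X")
  expect_identical(anon$header$start_date, as.Date("2001-01-01"))
  expect_identical(anon$header$start_time, "13.45.00")  # time kept
  expect_identical(anon$channels, rec$channels)
  expect_identical(anon$annotations, rec$annotations)
  expect_identical(anon$header$signal_headers, rec$header$signal_headers)
  expect_identical(anonymize_edf(anon), anon)

  part <- anonymize_edf(rec, patient_field = "ID042")
  expect_identical(part$header$patient_field, "ID042")
  expect_identical(part$header$recording_field, "Startdate X X X X X")
  expect_identical(part$header$start_date, as.Date("2001-01-01"))

  expect_error(anonymize_edf(rec, patient_field = strrep("x", 81)),
               class = "edfviz_validation_error")
})

test_that("prediction channels round trip through the EDF file", {
  rec <- make_test_recording(duration = 10)
  # values on the 16-bit quantisation grid of the [0, 1] range
  vals <- c(0, 0.2, 0.4, 1, 0.6, 0.8, 0.2, 0, 1, 0.4)
  p <- prediction_set(vals, n_samples = 2000, sample_rate = 200)
  aug <- append_prediction_channels(rec, p)

  expect_equal(length(aug$channels), 6L)
  added <- aug$channels[["PRED subject"]]
  expect_equal(length(added), 2000L)
  expect_equal(added, rep(vals, each = 200))
  expect_identical(aug$channels[1:5], rec$channels)

  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(aug, f)
  back <- prediction_channels(read_edf(f), window_samples = 200)
  expect_identical(rownames(back), "subject")
  expect_equal(as.vector(back), vals)

  # channel-wise predictions: one new channel per row, in row order
  m <- matrix(runif(5 * 10), nrow = 5)
  pc <- prediction_set(m, n_samples = 2000, sample_rate = 200, n_channels = 5,
                       row_names = names(rec$channels))
  aug2 <- append_prediction_channels(rec, pc)
  expect_equal(names(aug2$channels)[6:10],
               paste("PRED", names(rec$channels)))
})

test_that("prediction channel label collisions are disambiguated", {
  rec <- make_test_recording(duration = 2)
  p <- prediction_set(c(0.5, 0.6), n_samples = 400, sample_rate = 200,
                      row_names = "subject")
  aug <- append_prediction_channels(rec, p)
  expect_warning(
    aug2 <- append_prediction_channels(aug, p),
    "collides"
  )
  expect_true("PRED subject~2" %in% names(aug2$channels))
})
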