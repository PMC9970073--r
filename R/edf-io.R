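# EDF/EDF+C 16-bit codec, including the "EDF Annotations" TAL channel.
#
# Layout per the published format: a 256-byte fixed header, then 256 bytes
# of per-signal header fields (each field stored contiguously for all
# signals), then data records of interleaved little-endian int16 blocks.

EDF_ANNOT_LABEL <- "EDF Annotations"

ascii_field <- function(x, width) {
  x <- as.character(x)[1L]
  if (is.na(x)) x <- ""
  raw <- charToRaw(x)
  raw[raw > as.raw(126) | raw < as.raw(32)] <- charToRaw("?")  # US-ASCII only
  x <- rawToChar(raw)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space padded
}

# numeric -> at most `width` ASCII chars, plain decimal notation
num_field <- function(x, width = 8L) {
  for (d in seq(10L, 1L)) {
    s <- formatC(signif(x, d), format = "fg", width = 1L, flag = "-")
    s <- sub("\\.$", "", s)
    if (nchar(s) <= width && !grepl("e", s, fixed = TRUE)) {
      return(formatC(s, width = -width))
    }
  }
  stop_edfviz("cannot format ", x, " into ", width, " EDF header bytes",
              class = "edfviz_format_error")
}

parse_header_num <- function(s, field, integer = FALSE) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (any(is.na(v))) {
    stop_edfviz("malformed EDF header: field '", field, "' is not numeric (",
                deparse(trimws(s[is.na(v)][1L])), ")",
                class = "edfviz_format_error")
  }
  if (integer) v <- as.integer(round(v))
  v
}

read_chars <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  if (length(raw) < n) {
    stop_edfviz("malformed EDF header: file truncated",
                class = "edfviz_format_error")
  }
  rawToChar(raw)
}

read_char_fields <- function(con, ns, width) {
  vapply(seq_len(ns), function(i) read_chars(con, width), character(1L))
}

#' Read an EDF/EDF+C file
#'
#' Decodes a 16-bit EDF or continuous EDF+ file into an [eeg_recording()].
#' Samples are converted from digital to physical units with the standard
#' linear scaling
#' `physical = (digital - digital_min) * (physical_max - physical_min) /
#' (digital_max - digital_min) + physical_min`.
#' An `"EDF Annotations"` signal, if present, is parsed as a time-stamped
#' annotation list (TAL) and returned in `$annotations` rather than as a
#' channel.
#'
#' @param path path to an existing EDF/EDF+C file.
#' @return An [eeg_recording()].
#' @section Errors: malformed headers raise a format error naming the
#'   offending field; discontinuous (`EDF+D`) files are rejected as an
#'   unsupported dialect.
#' @seealso [write_edf()], [anonymize_edf()]
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    stop_edfviz("file not found: ", path, class = "edfviz_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))

  version <- trimws(read_chars(con, 8L))
  patient_field <- sub("\\s+$", "", read_chars(con, 80L))
  recording_field <- sub("\\s+$", "", read_chars(con, 80L))
  start_date_s <- trimws(read_chars(con, 8L))
  start_time_s <- trimws(read_chars(con, 8L))
  header_bytes <- parse_header_num(read_chars(con, 8L), "header bytes", TRUE)
  reserved <- trimws(read_chars(con, 44L))
  n_records <- parse_header_num(read_chars(con, 8L), "number of records", TRUE)
  record_duration <- parse_header_num(read_chars(con, 8L), "record duration")
  ns <- parse_header_num(read_chars(con, 4L), "number of signals", TRUE)

  if (startsWith(reserved, "EDF+D")) {
    stop_edfviz("discontinuous EDF+D files are not supported",
                class = "edfviz_unsupported_error")
  }
  if (ns < 1L) {
    stop_edfviz("malformed EDF header: field 'number of signals' is ", ns,
                class = "edfviz_format_error")
  }
  if (header_bytes != 256L + 256L * ns) {
    stop_edfviz("malformed EDF header: field 'header bytes' is ",
                header_bytes, ", expected ", 256L + 256L * ns,
                class = "edfviz_format_error")
  }
  if (record_duration <= 0) {
    stop_edfviz("malformed EDF header: field 'record duration' must be > 0",
                class = "edfviz_format_error")
  }
  if (n_records < 0L) {
    stop_edfviz("malformed EDF header: field 'number of records' is negative",
                class = "edfviz_format_error")
  }

  labels <- sub("\\s+$", "", read_char_fields(con, ns, 16L))
  transducer <- sub("\\s+$", "", read_char_fields(con, ns, 80L))
  phys_dim <- trimws(read_char_fields(con, ns, 8L))
  phys_min <- parse_header_num(read_char_fields(con, ns, 8L), "physical minimum")
  phys_max <- parse_header_num(read_char_fields(con, ns, 8L), "physical maximum")
  dig_min <- parse_header_num(read_char_fields(con, ns, 8L), "digital minimum", TRUE)
  dig_max <- parse_header_num(read_char_fields(con, ns, 8L), "digital maximum", TRUE)
  prefilter <- sub("\\s+$", "", read_char_fields(con, ns, 80L))
  spr <- parse_header_num(read_char_fields(con, ns, 8L), "samples per record", TRUE)
  read_chars(con, 32L * ns)  # reserved

  if (any(dig_min >= dig_max)) {
    stop_edfviz("malformed EDF header: field 'digital minimum' >= ",
                "'digital maximum'", class = "edfviz_format_error")
  }
  if (any(phys_min == phys_max)) {
    stop_edfviz("malformed EDF header: field 'physical minimum' equals ",
                "'physical maximum'", class = "edfviz_format_error")
  }
  if (any(spr < 1L)) {
    stop_edfviz("malformed EDF header: field 'samples per record' must be ",
                "positive", class = "edfviz_format_error")
  }

  rec_len <- sum(spr)
  raw_data <- readBin(con, "raw", n = 2L * rec_len * n_records)
  if (length(raw_data) < 2L * rec_len * n_records) {
    stop_edfviz("EDF data section truncated: expected ",
                2L * rec_len * n_records, " bytes, got ", length(raw_data),
                class = "edfviz_format_error")
  }

  is_annot <- trimws(labels) == EDF_ANNOT_LABEL
  offsets <- c(0L, cumsum(spr))  # sample offsets within a record
  rec_starts <- (seq_len(max(n_records, 0L)) - 1L) * 2L * rec_len

  channels <- list()
  sample_rates <- numeric(0)
  keep <- which(!is_annot)
  for (j in keep) {
    # byte indices of signal j inside every record
    within <- seq.int(2L * offsets[j] + 1L, 2L * offsets[j + 1L])
    idx <- as.vector(outer(within, rec_starts, `+`))
    dig <- readBin(raw_data[idx], "integer", n = spr[j] * n_records,
                   size = 2L, endian = "little", signed = TRUE)
    scale <- (phys_max[j] - phys_min[j]) / (dig_max[j] - dig_min[j])
    channels[[labels[j]]] <- (dig - dig_min[j]) * scale + phys_min[j]
    sample_rates <- c(sample_rates, spr[j] / record_duration)
  }

  annotations <- data.frame(onset = numeric(), duration = numeric(),
                            text = character(), stringsAsFactors = FALSE)
  for (j in which(is_annot)) {
    within <- seq.int(2L * offsets[j] + 1L, 2L * offsets[j + 1L])
    tals <- lapply(rec_starts, function(s) parse_tal(raw_data[within + s]))
    annotations <- rbind(annotations, do.call(rbind, tals))
  }
  if (nrow(annotations)) {
    annotations <- annotations[order(annotations$onset), , drop = FALSE]
    rownames(annotations) <- NULL
  }

  start_date <- parse_edf_date(start_date_s)
  sh <- data.frame(
    label = labels[keep],
    transducer = transducer[keep],
    physical_dimension = phys_dim[keep],
    physical_min = phys_min[keep],
    physical_max = phys_max[keep],
    digital_min = dig_min[keep],
    digital_max = dig_max[keep],
    prefiltering = prefilter[keep],
    samples_per_record = spr[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      header = list(
        version = version,
        patient_field = patient_field,
        recording_field = recording_field,
        start_date = start_date,
        start_time = start_time_s,
        n_records = n_records,
        record_duration = record_duration,
        reserved = reserved,
        signal_headers = sh
      ),
      channels = channels,
      sample_rates = sample_rates,
      annotations = annotations
    ),
    class = "eeg_recording"
  )
}

parse_edf_date <- function(s) {
  parts <- strsplit(s, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) return(as.Date("2001-01-01"))
  yy <- suppressWarnings(as.integer(parts[3L]))
  if (is.na(yy)) return(as.Date("2001-01-01"))
  year <- if (yy >= 85) 1900L + yy else 2000L + yy  # EDF clipping convention
  out <- suppressWarnings(as.Date(sprintf("%04d-%s-%s", year, parts[2L], parts[1L])))
  if (is.na(out)) as.Date("2001-01-01") else out
}

# ---- TAL codec -------------------------------------------------------------

TAL_SEP <- as.raw(0x14)   # onset/text delimiter
TAL_DUR <- as.raw(0x15)   # onset/duration delimiter

format_tal_onset <- function(x) {
  s <- formatC(x, format = "f", digits = 3L)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  if (!startsWith(s, "-")) s <- paste0("+", s)
  s
}

# Serialise one data record's annotation block: the mandatory timekeeping
# TAL followed by any annotations whose onset falls in this record.
format_tal_record <- function(record_onset, ann) {
  out <- c(charToRaw(format_tal_onset(record_onset)), TAL_SEP, TAL_SEP, as.raw(0L))
  if (NROW(ann)) {
    for (i in seq_len(nrow(ann))) {
      chunk <- charToRaw(format_tal_onset(ann$onset[i]))
      if (!is.na(ann$duration[i])) {
        chunk <- c(chunk, TAL_DUR,
                   charToRaw(sub("^\\+", "", format_tal_onset(ann$duration[i]))))
      }
      chunk <- c(chunk, TAL_SEP, charToRaw(enc2utf8(ann$text[i])), TAL_SEP, as.raw(0L))
      out <- c(out, chunk)
    }
  }
  out
}

# Parse one record's annotation bytes into a data frame (timekeeping TALs,
# which carry no text, are dropped).
parse_tal <- function(bytes) {
  empty <- data.frame(onset = numeric(), duration = numeric(),
                      text = character(), stringsAsFactors = FALSE)
  nul <- which(bytes == as.raw(0L))
  if (!length(nul)) return(empty)
  starts <- c(1L, head(nul, -1L) + 1L)
  ends <- nul - 1L
  onsets <- numeric(0); durations <- numeric(0); texts <- character(0)
  for (k in seq_along(starts)) {
    if (ends[k] < starts[k]) next
    chunk <- bytes[starts[k]:ends[k]]
    seps <- which(chunk == TAL_SEP)
    if (length(seps) < 2L) next
    stamp <- chunk[seq_len(seps[1L] - 1L)]
    dsep <- which(stamp == TAL_DUR)
    if (length(dsep)) {
      onset <- as.numeric(rawToChar(stamp[seq_len(dsep[1L] - 1L)]))
      duration <- as.numeric(rawToChar(stamp[(dsep[1L] + 1L):length(stamp)]))
    } else {
      onset <- as.numeric(rawToChar(stamp))
      duration <- NA_real_
    }
    if (is.na(onset)) next
    # one TAL may carry several \x14-separated texts
    bounds <- c(seps, length(chunk) + 1L)
    for (t in seq_len(length(seps) - 1L)) {
      lo <- seps[t] + 1L
      hi <- seps[t + 1L] - 1L
      txt <- if (hi >= lo) {
        x <- rawToChar(chunk[lo:hi]); Encoding(x) <- "UTF-8"; x
      } else ""
      if (nzchar(txt)) {
        onsets <- c(onsets, onset)
        durations <- c(durations, duration)
        texts <- c(texts, txt)
      }
    }
  }
  if (!length(onsets)) return(empty)
  data.frame(onset = onsets, duration = durations, text = texts,
             stringsAsFactors = FALSE)
}

# ---- writing ---------------------------------------------------------------

#' Write an EDF+C file
#'
#' Serialises an [eeg_recording()] as a continuous EDF+ file. Signal data
#' are quantised to 16-bit integers using each channel's physical/digital
#' ranges; physical values outside `[physical_min, physical_max]` are
#' clipped (with a warning reporting the count). Annotations are stored in
#' an `"EDF Annotations"` signal as TAL records, each annotation in the
#' data record containing its onset; onsets are serialised with millisecond
#' resolution. Header text is coerced to US-ASCII (non-ASCII bytes become
#' `"?"`).
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(recording, path) {
  validate_recording(recording)
  h <- recording$header
  sh <- h$signal_headers
  n_rec <- h$n_records
  rd <- h$record_duration

  # annotation channel sizing: every record holds its timekeeping TAL plus
  # the annotations starting inside it
  ann <- recording$annotations
  rec_of <- if (NROW(ann)) pmin(floor(ann$onset / rd), n_rec - 1L) else integer(0)
  tal_records <- lapply(seq_len(n_rec) - 1L, function(r) {
    format_tal_record(r * rd, ann[rec_of == r, , drop = FALSE])
  })
  ann_spr <- max(8L, ceiling(max(vapply(tal_records, length, integer(1L)), 0L) / 2L))

  ns <- nrow(sh) + 1L
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar(ascii_field(h$version, 8L), con, eos = NULL)
  writeChar(ascii_field(h$patient_field, 80L), con, eos = NULL)
  writeChar(ascii_field(h$recording_field, 80L), con, eos = NULL)
  writeChar(ascii_field(format(h$start_date, "%d.%m.%y"), 8L), con, eos = NULL)
  writeChar(ascii_field(h$start_time, 8L), con, eos = NULL)
  writeChar(num_field(256L * (ns + 1L)), con, eos = NULL)
  writeChar(ascii_field("EDF+C", 44L), con, eos = NULL)
  writeChar(num_field(n_rec), con, eos = NULL)
  writeChar(num_field(rd), con, eos = NULL)
  writeChar(num_field(ns, 4L), con, eos = NULL)

  wfields <- function(values, width) {
    for (v in values) writeChar(ascii_field(v, width), con, eos = NULL)
  }
  wnum <- function(values) {
    for (v in values) writeChar(num_field(v), con, eos = NULL)
  }
  wfields(c(sh$label, EDF_ANNOT_LABEL), 16L)
  wfields(c(sh$transducer, ""), 80L)
  wfields(c(sh$physical_dimension, ""), 8L)
  wnum(c(sh$physical_min, -1))
  wnum(c(sh$physical_max, 1))
  wnum(c(sh$digital_min, -32768L))
  wnum(c(sh$digital_max, 32767L))
  wfields(c(sh$prefiltering, ""), 80L)
  wnum(c(sh$samples_per_record, ann_spr))
  wfields(rep("", ns), 32L)

  # quantise all channels up front
  n_clipped <- 0L
  digital <- vector("list", nrow(sh))
  for (j in seq_len(nrow(sh))) {
    x <- recording$channels[[j]]
    lo <- sh$physical_min[j]; hi <- sh$physical_max[j]
    clip <- x < min(lo, hi) | x > max(lo, hi)
    n_clipped <- n_clipped + sum(clip)
    x <- pmin(pmax(x, min(lo, hi)), max(lo, hi))
    scale <- (sh$digital_max[j] - sh$digital_min[j]) / (hi - lo)
    digital[[j]] <- as.integer(round((x - lo) * scale)) + sh$digital_min[j]
  }
  if (n_clipped > 0L) {
    warning(n_clipped, " sample(s) outside the physical range were clipped",
            call. = FALSE)
  }

  spr <- sh$samples_per_record
  for (r in seq_len(n_rec)) {
    for (j in seq_len(nrow(sh))) {
      seg <- digital[[j]][((r - 1L) * spr[j] + 1L):(r * spr[j])]
      writeBin(seg, con, size = 2L, endian = "little")
    }
    tal <- tal_records[[r]]
    writeBin(c(tal, raw(2L * ann_spr - length(tal))), con)
  }
  invisible(path)
}

# ---- de-identification -----------------------------------------------------

#' De-identify an EEG recording header
#'
#' Strips identifying information from the EDF header: by default the
#' patient field becomes `"X X X X"`, the recording field
#' `"Startdate X X X X X"`, and the start date the fixed sentinel
#' 01.01.2001. The time of day, all signal headers, the samples and the
#' annotations are left untouched. Individual fields can instead be set
#' explicitly via the override arguments.
#'
#' @param recording an [eeg_recording()].
#' @param patient_field,recording_field,start_date optional overrides; text
#'   fields are limited to 80 characters, `start_date` must be a `Date` (or
#'   coercible).
#' @return The de-identified [eeg_recording()].
#' @export
#' @examples
#' rec <- synth_recording(synth_spec(duration_sec = 2, seed = 1))
#' rec$header$patient_field <- "John Doe M 01-JAN-1980"
#' anonymize_edf(rec)$header$patient_field
anonymize_edf <- function(recording, patient_field = NULL,
                          recording_field = NULL, start_date = NULL) {
  validate_recording(recording)
  for (f in c(patient_field, recording_field)) {
    if (!is.null(f) && nchar(f) > 80L) {
      stop_edfviz("header override exceeds the 80-character EDF field limit",
                  class = "edfviz_validation_error")
    }
  }
  recording$header$patient_field <-
    if (is.null(patient_field)) "X X X X" else patient_field
  recording$header$recording_field <-
    if (is.null(recording_field)) "Startdate X X X X X" else recording_field
  recording$header$start_date <-
    if (is.null(start_date)) as.Date("2001-01-01") else as.Date(start_date)
  recording
}

# ---- prediction channels ---------------------------------------------------

#' Store window-wise predictions as extra EDF data channels
#'
#' Appends one channel per prediction row, labelled `"PRED "` followed by
#' the row name, holding each window's value repeated over the window's
#' sample span. The resulting recording round-trips through
#' [write_edf()]/[read_edf()] (values are 16-bit quantised on a
#' `[0, 1]` — or `[0, K]` for multiclass — physical range). Original
#' channels are unchanged. Label collisions are disambiguated with a
#' numeric suffix and a warning.
#'
#' @param recording an [eeg_recording()].
#' @param prediction_set a [prediction_set()] aligned to the recording.
#' @return The augmented [eeg_recording()].
#' @seealso [prediction_channels()] to extract them again.
#' @export
append_prediction_channels <- function(recording, prediction_set) {
  validate_recording(recording)
  stopifnot(inherits(prediction_set, "prediction_set"))
  p <- prediction_set
  n_samples <- p$n_windows * p$window_samples
  rd <- recording$header$record_duration
  spr <- p$sample_rate * rd
  if (abs(spr - round(spr)) > 1e-9 ||
      n_samples != recording$header$n_records * round(spr)) {
    stop_edfviz("prediction set is not aligned to the recording's records",
                class = "edfviz_alignment_error")
  }
  spr <- as.integer(round(spr))
  pmax_phys <- if (p$kind == "binary") 1 else max(1, p$n_classes)
  existing <- names(recording$channels)
  sh <- recording$header$signal_headers
  for (i in seq_len(nrow(p$values))) {
    lab <- substr(paste0("PRED ", p$row_names[i]), 1L, 16L)
    if (lab %in% existing) {
      k <- 2L
      repeat {
        cand <- substr(paste0(lab, "~", k), 1L, 16L)
        if (!cand %in% existing) break
        k <- k + 1L
      }
      warning("prediction channel label '", lab, "' collides; using '",
              cand, "'", call. = FALSE)
      lab <- cand
    }
    existing <- c(existing, lab)
    recording$channels[[lab]] <- rep(p$values[i, ], each = p$window_samples)
    recording$sample_rates <- c(recording$sample_rates, p$sample_rate)
    sh <- rbind(sh, data.frame(
      label = lab, transducer = "prediction",
      physical_dimension = "", physical_min = 0, physical_max = pmax_phys,
      digital_min = -32768L, digital_max = 32767L,
      prefiltering = "", samples_per_record = spr,
      stringsAsFactors = FALSE
    ))
  }
  recording$header$signal_headers <- sh
  validate_recording(recording)
  recording
}

#' Extract stored prediction channels as a matrix
#'
#' Recovers the window-wise prediction matrix from channels written by
#' [append_prediction_channels()] (labels starting `"PRED "`), assuming
#' constant values over each window span.
#'
#' @param recording an [eeg_recording()].
#' @param window_samples samples per prediction window.
#' @return numeric matrix, one row per `PRED` channel, with row names
#'   stripped of the `"PRED "` prefix.
#' @export
prediction_channels <- function(recording, window_samples) {
  stopifnot(is_count(window_samples))
  labs <- grep("^PRED ", names(recording$channels), value = TRUE)
  if (!length(labs)) {
    stop_edfviz("recording has no 'PRED ' channels",
                class = "edfviz_lookup_error")
  }
  rows <- lapply(labs, function(l) {
    x <- recording$channels[[l]]
    x[seq(1L, length(x), by = window_samples)]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- sub("^PRED ", "", labs)
  out
}
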