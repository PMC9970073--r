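#' Construct an EEG recording in memory
#'
#' An `eeg_recording` bundles decoded multi-channel signal data (in physical
#' units) with the EDF-style header metadata needed to serialise it and a
#' list of time-stamped text annotations. [read_edf()] returns this class;
#' [write_edf()] consumes it.
#'
#' @param channels named list of numeric vectors (one per channel, physical
#'   units, equal lengths per sample rate) or a numeric matrix with one
#'   column per channel and column names as labels.
#' @param sample_rate sampling rate in Hz; a scalar (recycled) or one value
#'   per channel. Must give a whole number of samples per record.
#' @param annotations optional data frame with columns `onset` (seconds from
#'   recording start), `duration` (seconds, `NA` for instantaneous) and
#'   `text`.
#' @param record_duration EDF data-record duration in seconds (default 1).
#' @param physical_range length-2 numeric, the physical min/max stored in
#'   the header and used for 16-bit quantisation on write. Default spans
#'   the data symmetrically, padded 5\% and rounded up.
#' @param physical_dimension unit string written to the header, default
#'   `"uV"`.
#' @param patient_field,recording_field free-text EDF header fields
#'   (max 80 characters each).
#' @param start_date a `Date` (EDF start date).
#' @param start_time start time of day as `"HH.MM.SS"`.
#'
#' @return An object of class `eeg_recording`: a list with elements
#'   `header` (including a `signal_headers` data frame), `channels` (named
#'   list of numeric vectors), `sample_rates`, and `annotations`.
#' @seealso [read_edf()], [write_edf()], [synth_recording()]
#' @export
#' @examples
#' rec <- eeg_recording(list(C3 = sin(2 * pi * 10 * seq(0, 1, by = 1 / 200))[-1]),
#'                      sample_rate = 200)
#' rec
eeg_recording <- function(channels, sample_rate, annotations = NULL,
                          record_duration = 1, physical_range = NULL,
                          physical_dimension = "uV",
                          patient_field = "X X X X",
                          recording_field = "Startdate X X X X X",
                          start_date = as.Date("2001-01-01"),
                          start_time = "00.00.00") {
  if (is.matrix(channels)) {
    channels <- stats::setNames(
      lapply(seq_len(ncol(channels)), function(j) channels[, j]),
      colnames(channels)
    )
  }
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop_edfviz("`channels` must be a non-empty named list of numeric vectors",
                class = "edfviz_structure_error")
  }
  nch <- length(channels)
  sample_rate <- rep_len(sample_rate, nch)
  if (any(sample_rate <= 0)) {
    stop_edfviz("sample rates must be positive", class = "edfviz_structure_error")
  }
  spr <- sample_rate * record_duration
  if (any(abs(spr - round(spr)) > 1e-9)) {
    stop_edfviz("sample_rate * record_duration must be a whole number of ",
                "samples per record", class = "edfviz_structure_error")
  }
  spr <- as.integer(round(spr))
  n_rec <- length(channels[[1L]]) / spr[1L]
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop_edfviz("channel length not a whole number of records; adjust ",
                "record_duration", class = "edfviz_structure_error")
  }
  n_rec <- as.integer(round(n_rec))
  for (j in seq_len(nch)) {
    if (length(channels[[j]]) != n_rec * spr[j]) {
      stop_edfviz("channel '", names(channels)[j], "' has ",
                  length(channels[[j]]), " samples; expected ", n_rec * spr[j],
                  class = "edfviz_structure_error")
    }
  }
  if (is.null(physical_range)) {
    m <- max(1, max(abs(unlist(channels, use.names = FALSE)), na.rm = TRUE))
    m <- ceiling(m * 1.05)
    physical_range <- c(-m, m)
  }
  sh <- data.frame(
    label = substr(names(channels), 1L, 16L),
    transducer = "",
    physical_dimension = physical_dimension,
    physical_min = physical_range[1L],
    physical_max = physical_range[2L],
    digital_min = -32768L,
    digital_max = 32767L,
    prefiltering = "",
    samples_per_record = spr,
    stringsAsFactors = FALSE
  )
  ann <- normalize_annotations(annotations, n_rec * record_duration)
  rec <- structure(
    list(
      header = list(
        version = "0",
        patient_field = patient_field,
        recording_field = recording_field,
        start_date = start_date,
        start_time = start_time,
        n_records = n_rec,
        record_duration = record_duration,
        reserved = "EDF+C",
        signal_headers = sh
      ),
      channels = channels,
      sample_rates = sample_rate,
      annotations = ann
    ),
    class = "eeg_recording"
  )
  validate_recording(rec)
  rec
}

normalize_annotations <- function(annotations, total_duration) {
  if (is.null(annotations) || NROW(annotations) == 0L) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      text = character(), stringsAsFactors = FALSE))
  }
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (!all(c("onset", "text") %in% names(ann))) {
    stop_edfviz("annotations need columns `onset` and `text`",
                class = "edfviz_structure_error")
  }
  if (is.null(ann$duration)) ann$duration <- NA_real_
  ann <- ann[c("onset", "duration", "text")]
  ann$onset <- as.numeric(ann$onset)
  ann$duration <- as.numeric(ann$duration)
  ann$text <- as.character(ann$text)
  if (any(ann$onset < 0)) {
    stop_edfviz("annotation onsets must be >= 0", class = "edfviz_structure_error")
  }
  dur <- ifelse(is.na(ann$duration), 0, ann$duration)
  if (any(dur < 0)) {
    stop_edfviz("annotation durations must be >= 0",
                class = "edfviz_structure_error")
  }
  if (any(ann$onset + dur > total_duration + 1e-9)) {
    stop_edfviz("annotation extends past end of recording",
                class = "edfviz_structure_error")
  }
  ann <- ann[order(ann$onset), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  h <- rec$header
  sh <- h$signal_headers
  if (nrow(sh) != length(rec$channels)) {
    stop_edfviz("signal_headers rows must match channel count",
                class = "edfviz_structure_error")
  }
  if (any(sh$digital_min >= sh$digital_max)) {
    stop_edfviz("digital_min must be < digital_max",
                class = "edfviz_structure_error")
  }
  if (any(sh$physical_min == sh$physical_max)) {
    stop_edfviz("physical_min must differ from physical_max",
                class = "edfviz_structure_error")
  }
  labs <- trimws(gsub("\\s+", " ", sh$label))
  if (anyDuplicated(labs)) {
    stop_edfviz("channel labels must be unique: ",
                paste(labs[duplicated(labs)], collapse = ", "),
                class = "edfviz_structure_error")
  }
  for (j in seq_along(rec$channels)) {
    if (length(rec$channels[[j]]) != h$n_records * sh$samples_per_record[j]) {
      stop_edfviz("channel '", sh$label[j], "' sample count inconsistent ",
                  "with n_records", class = "edfviz_structure_error")
    }
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  h <- x$header
  cat("<eeg_recording> ", length(x$channels), " channel(s), ",
      num_str(recording_duration(x)), " s\n", sep = "")
  cat("  start: ", format(h$start_date, "%d.%m.%Y"), " ", h$start_time,
      "   records: ", h$n_records, " x ", num_str(h$record_duration), " s\n",
      sep = "")
  rates <- paste(unique(num_str(x$sample_rates)), collapse = ", ")
  cat("  sample rate(s): ", rates, " Hz\n", sep = "")
  labs <- names(x$channels)
  if (length(labs) > 8) labs <- c(labs[1:8], "...")
  cat("  channels: ", paste(labs, collapse = ", "), "\n", sep = "")
  cat("  annotations: ", nrow(x$annotations), "\n", sep = "")
  invisible(x)
}

#' Total duration of a recording in seconds
#' @param recording an [eeg_recording()].
#' @return numeric scalar, seconds.
#' @export
recording_duration <- function(recording) {
  recording$header$n_records * recording$header$record_duration
}

#' Channel labels of a recording
#' @inheritParams recording_duration
#' @return character vector of labels in file order.
#' @export
channel_labels <- function(recording) {
  names(recording$channels)
}
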