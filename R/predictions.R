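# Window-wise model predictions: loading, validation, alignment to the
# sample clock, smoothing, and thresholding into per-sample masks.

#' Construct a prediction set
#'
#' A `prediction_set` holds a matrix of window-wise classifier outputs plus
#' the alignment metadata mapping each window to a span of EEG samples.
#' Binary predictions are soft scores in `[0, 1]` (0 = baseline, 1 =
#' condition of interest); multiclass predictions are integer class ids in
#' `{0, ..., K}` with 0 the baseline class. A single row is a subject-level
#' prediction; `n_channels` rows are channel-wise predictions in plot
#' order.
#'
#' @param values numeric matrix (rows x windows) or vector (one row).
#' @param n_samples number of EEG samples the predictions cover; must be an
#'   exact multiple of the number of windows.
#' @param sample_rate EEG sampling rate in Hz.
#' @param n_channels number of plotted channels (used to validate a
#'   channel-wise row count); `NULL` accepts only subject scope.
#' @param kind `"binary"` or `"multiclass"`.
#' @param row_names optional row labels (default `"subject"` or the channel
#'   index).
#' @param provenance optional identifier of the producing model.
#' @return An object of class `prediction_set`.
#' @export
prediction_set <- function(values, n_samples, sample_rate,
                           n_channels = NULL, kind = c("binary", "multiclass"),
                           row_names = NULL, provenance = NULL) {
  kind <- match.arg(kind)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  stopifnot(is.matrix(values), is_count(n_samples), is_number(sample_rate))
  if (anyNA(values) || any(!is.finite(values))) {
    stop_edfviz("predictions contain NA/NaN/Inf values",
                class = "edfviz_validation_error")
  }
  nr <- nrow(values)
  m <- ncol(values)
  if (nr == 1L) {
    row_scope <- "subject"
  } else if (!is.null(n_channels) && nr == n_channels) {
    row_scope <- "channelwise"
  } else {
    stop_edfviz("prediction matrix has ", nr, " row(s); expected 1 ",
                "(subject-level)",
                if (!is.null(n_channels)) paste0(" or ", n_channels,
                                                 " (channel-wise)"),
                class = "edfviz_shape_error")
  }
  if (n_samples %% m != 0L) {
    stop_edfviz(m, " windows do not divide ", n_samples, " samples evenly",
                class = "edfviz_alignment_error")
  }
  n_classes <- 0L
  if (kind == "binary") {
    if (any(values < 0 | values > 1)) {
      stop_edfviz("binary predictions must lie in [0, 1]",
                  class = "edfviz_range_error")
    }
  } else {
    if (any(values != round(values)) || any(values < 0)) {
      stop_edfviz("multiclass predictions must be integers >= 0 ",
                  "(0 = baseline class)", class = "edfviz_range_error")
    }
    n_classes <- as.integer(max(values))
  }
  if (is.null(row_names)) {
    row_names <- if (row_scope == "subject") "subject" else
      sprintf("ch%02d", seq_len(nr))
  }
  structure(
    list(values = unname(values), kind = kind, row_scope = row_scope,
         n_windows = m, window_samples = as.integer(n_samples / m),
         sample_rate = sample_rate, n_classes = n_classes,
         row_names = row_names, provenance = provenance),
    class = "prediction_set"
  )
}

#' @export
print.prediction_set <- function(x, ...) {
  cat("<prediction_set> ", nrow(x$values), " row(s) x ", x$n_windows,
      " windows (", x$kind, ", ", x$row_scope, ")\n", sep = "")
  cat("  window: ", x$window_samples, " samples = ",
      num_str(x$window_samples / x$sample_rate), " s at ",
      num_str(x$sample_rate), " Hz\n", sep = "")
  if (!is.null(x$provenance)) cat("  source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Load a prediction matrix from a text file
#'
#' Reads a plaintext numeric matrix (comma- or whitespace-delimited, all
#' rows the same length) and aligns it against a recording: one row is a
#' subject-level prediction, `n_channels` rows are channel-wise. The number
#' of windows must divide `n_samples` exactly.
#'
#' @param path path to the text file.
#' @inheritParams prediction_set
#' @return A [prediction_set()].
#' @export
load_prediction_file <- function(path, n_samples, sample_rate,
                                 n_channels = NULL,
                                 kind = c("binary", "multiclass")) {
  if (!file.exists(path)) {
    stop_edfviz("prediction file not found: ", path, class = "edfviz_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "[,[:space:]]+")[[1L]]
    v <- suppressWarnings(as.numeric(toks))
    if (anyNA(v)) {
      stop_edfviz("non-numeric value in prediction file: ", path,
                  class = "edfviz_validation_error")
    }
    v
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    stop_edfviz("prediction file rows have unequal lengths: ",
                paste(unique(lens), collapse = ", "),
                class = "edfviz_shape_error")
  }
  prediction_set(do.call(rbind, rows), n_samples, sample_rate,
                 n_channels = n_channels, kind = kind,
                 provenance = basename(path))
}

#' Run an external predictor through the adapter contract
#'
#' A predictor is either an in-process R function or a shell command. A
#' function receives `input` and must return a numeric matrix of
#' window-wise outputs; a command is run with `input` written to a
#' temporary file passed as its final argument, and must print the matrix
#' to standard output. The output is validated exactly as
#' [load_prediction_file()] and the predictor id is recorded as
#' provenance.
#'
#' @param predictor function or command string.
#' @param input object handed to the predictor (e.g. a feature matrix).
#' @inheritParams prediction_set
#' @return A [prediction_set()].
#' @export
run_external_predictor <- function(predictor, input, n_samples, sample_rate,
                                   n_channels = NULL,
                                   kind = c("binary", "multiclass")) {
  if (is.function(predictor)) {
    out <- predictor(input)
    id <- "<function>"
  } else if (is.character(predictor) && length(predictor) == 1L) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    utils::write.table(input, tmp, row.names = FALSE, col.names = FALSE)
    txt <- system2(predictor[1L], args = tmp, stdout = TRUE)
    out <- do.call(rbind, lapply(txt, function(l) {
      as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1L]])
    }))
    id <- predictor
  } else {
    stop_edfviz("`predictor` must be a function or a command string",
                class = "edfviz_validation_error")
  }
  if (is.vector(out)) out <- matrix(out, nrow = 1L)
  if (!is.numeric(out)) {
    stop_edfviz("predictor output is not numeric",
                class = "edfviz_validation_error")
  }
  prediction_set(out, n_samples, sample_rate, n_channels = n_channels,
                 kind = kind, provenance = id)
}

#' Smooth binary prediction scores
#'
#' Averages consecutive windows to reduce noise in the final predictions.
#' The default is a trailing (causal) moving average of width `k`: output
#' window `i` averages windows `max(1, i-k+1) ... i`, so the first `k - 1`
#' outputs shrink to the available history and length is preserved.
#' `method = "block"` instead averages non-overlapping blocks of `k`
#' windows and assigns each block mean to all its windows.
#'
#' @param pset a binary [prediction_set()].
#' @param k number of consecutive windows to average (default 20).
#' @param method `"trailing"` (default) or `"block"`.
#' @return A [prediction_set()] with smoothed values.
#' @export
smooth_predictions <- function(pset, k = 20L, method = c("trailing", "block")) {
  stopifnot(inherits(pset, "prediction_set"))
  method <- match.arg(method)
  if (!is_count(k)) {
    stop_edfviz("`k` must be a positive integer", class = "edfviz_validation_error")
  }
  if (pset$kind != "binary") {
    stop_edfviz("smoothing is defined for binary scores only",
                class = "edfviz_unsupported_error")
  }
  if (k == 1L) return(pset)
  m <- pset$n_windows
  sm <- t(apply(pset$values, 1L, function(x) {
    if (method == "trailing") {
      cs <- cumsum(x)
      lag <- c(rep(0, min(k, m)), cs[seq_len(max(0L, m - k))])
      width <- pmin(seq_len(m), k)
      (cs - lag) / width
    } else {
      blk <- rep(seq_len(ceiling(m / k)), each = k)[seq_len(m)]
      stats::ave(x, blk)
    }
  }))
  pset$values <- matrix(sm, nrow = nrow(pset$values))
  pset
}

#' Threshold predictions into a per-sample mask
#'
#' Expands window verdicts onto the EEG sample clock. For binary scores a
#' window is positive when its score is at or above the threshold (so
#' threshold 0 marks everything positive); the verdict is repeated over the
#' window's `window_samples` samples. For multiclass sets the threshold is
#' ignored and the mask holds integer class ids.
#'
#' @param pset a [prediction_set()].
#' @param threshold detection threshold in `[0, 1]` (binary only).
#' @return An object of class `sample_mask`: a logical (binary) or integer
#'   (multiclass) matrix with one row per prediction row and one column per
#'   EEG sample, with attributes `window_samples` and `row_scope`.
#' @export
#' @examples
#' p <- prediction_set(c(0.2, 0.8), n_samples = 6, sample_rate = 1)
#' as.vector(to_sample_mask(p, 0.5))  # F F F T T T
to_sample_mask <- function(pset, threshold = 0.5) {
  stopifnot(inherits(pset, "prediction_set"))
  if (pset$kind == "binary") {
    if (!is_number(threshold) || threshold < 0 || threshold > 1) {
      stop_edfviz("threshold must lie in [0, 1]", class = "edfviz_range_error")
    }
    v <- pset$values >= threshold
  } else {
    v <- pset$values
  }
  mask <- v[, rep(seq_len(pset$n_windows), each = pset$window_samples),
            drop = FALSE]
  structure(mask, window_samples = pset$window_samples,
            row_scope = pset$row_scope, class = c("sample_mask", class(mask)))
}
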