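# Seizure-detection evaluation protocol: false-positive-budget threshold
# calibration, window-level metrics (AUC-ROC, AUC-PR, sensitivity,
# specificity), event-level metrics (event sensitivity, false-positive
# duration per hour, onset latency) and per-patient aggregation.

#' Construct a normalized set of half-open time intervals
#'
#' Intervals are `[start, end)` in seconds on the recording clock. They are
#' sorted and overlapping/abutting intervals are merged, so the result is
#' pairwise disjoint.
#'
#' @param start,end numeric vectors of equal length, `start < end`.
#' @return An object of class `interval_set`: a 2-column matrix
#'   (`start`, `end`).
#' @export
#' @examples
#' interval_set(c(5, 1, 2), c(6, 2.5, 3))  # [1,3) merged, [5,6)
interval_set <- function(start = numeric(), end = numeric()) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == length(end))
  if (any(start >= end)) {
    stop_edfviz("every interval needs start < end",
                class = "edfviz_validation_error")
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  i <- 1L
  while (i < length(start)) {
    if (start[i + 1L] <= end[i]) {   # overlap or abut: merge
      end[i] <- max(end[i], end[i + 1L])
      start <- start[-(i + 1L)]; end <- end[-(i + 1L)]
    } else {
      i <- i + 1L
    }
  }
  structure(cbind(start = start, end = end), class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set> ", nrow(x), " interval(s), total ",
      num_str(sum(x[, "end"] - x[, "start"])), " s\n", sep = "")
  if (nrow(x)) {
    shown <- head(seq_len(nrow(x)), 10L)
    cat(paste0("  [", num_str(x[shown, "start"]), ", ",
               num_str(x[shown, "end"]), ")", collapse = "\n"), "\n")
    if (nrow(x) > 10L) cat("  ...\n")
  }
  invisible(x)
}

# overlap indicator between one interval and the rows of an interval set
intersects <- function(iv, set) {
  if (!NROW(set)) return(logical(0))
  set[, "start"] < iv[2L] & set[, "end"] > iv[1L]
}

#' Calibrate a detection threshold against a false-positive budget
#'
#' Chooses the detection threshold on training scores so that the time
#' classified as positive on baseline (label 0) windows does not exceed a
#' fixed allowance — by default two minutes of false positives per hour.
#' Candidate thresholds are the unique score values plus 1.0, ascending;
#' the smallest feasible candidate is returned, which maximises sensitivity
#' subject to the budget (the classification rule is score >= threshold).
#' False-positive time is denominated per hour of baseline time by
#' default; set `denominator = "total"` for per hour of total record time.
#'
#' @param scores numeric vector of (already smoothed) window scores.
#' @param labels binary 0/1 window labels (1 = event).
#' @param window_sec seconds per window (default 1).
#' @param fp_budget_min_per_hr allowed minutes of false positives per hour
#'   (default 2).
#' @param denominator `"baseline"` (default) or `"total"`.
#' @return The calibrated threshold in `[0, 1]`. If even the largest
#'   candidate exceeds the budget (only possible when baseline windows
#'   score exactly 1), 1.0 is returned with a warning.
#' @export
calibrate_threshold <- function(scores, labels, window_sec = 1,
                                fp_budget_min_per_hr = 2,
                                denominator = c("baseline", "total")) {
  denominator <- match.arg(denominator)
  stopifnot(length(scores) == length(labels), length(scores) > 0,
            all(labels %in% c(0, 1)), is_number(window_sec), window_sec > 0)
  cand <- sort(unique(c(scores, 1)))
  neg <- sort(scores[labels == 0])
  hours <- switch(denominator,
                  baseline = length(neg) * window_sec / 3600,
                  total = length(scores) * window_sec / 3600)
  if (hours == 0) return(cand[1L])  # no baseline: any threshold is feasible
  # FP windows at threshold t: #(neg >= t), via position in the sorted negs
  fp_counts <- length(neg) - findInterval(cand, neg, left.open = TRUE)
  fp_rate <- fp_counts * window_sec / 60 / hours
  feasible <- which(fp_rate <= fp_budget_min_per_hr)
  if (!length(feasible)) {
    warning("no threshold meets the false-positive budget (baseline scores ",
            "at 1.0); returning 1.0", call. = FALSE)
    return(1)
  }
  cand[feasible[1L]]
}

#' Window-level detection metrics
#'
#' Treats window scores as independent outputs. AUC-ROC is the
#' Mann-Whitney pairwise statistic (ties count one half); AUC-PR is
#' average precision with step interpolation. Sensitivity and specificity
#' use the rule score >= threshold. With only one class present the AUCs
#' are `NA` and the defined rate is still computed.
#'
#' @inheritParams calibrate_threshold
#' @param threshold detection threshold.
#' @return list with `auc_roc`, `auc_pr`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' window_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), 0.5)$auc_roc  # 0.75
window_metrics <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pos <- labels == 1
  npos <- sum(pos); nneg <- sum(!pos)
  auc_roc <- auc_pr <- NA_real_
  if (npos > 0 && nneg > 0) {
    r <- rank(scores)  # midranks: ties contribute 1/2
    auc_roc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
    auc_pr <- average_precision(scores, labels)
  }
  verdict <- scores >= threshold
  list(
    auc_roc = auc_roc,
    auc_pr = auc_pr,
    sensitivity = if (npos > 0) sum(verdict & pos) / npos else NA_real_,
    specificity = if (nneg > 0) sum(!verdict & !pos) / nneg else NA_real_
  )
}

# average precision over descending unique score thresholds:
# AP = sum_i (R_i - R_{i-1}) * P_i
average_precision <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  tp <- vapply(th, function(t) sum(labels == 1 & scores >= t), numeric(1L))
  pp <- vapply(th, function(t) sum(scores >= t), numeric(1L))
  recall <- tp / npos
  precision <- tp / pp
  sum(diff(c(0, recall)) * precision)
}

#' Contiguous detection intervals from window verdicts
#'
#' Maximal runs of positive windows become half-open intervals on the
#' recording clock; runs separated by gaps of at most `merge_gap_sec` are
#' merged.
#'
#' @param verdicts logical or 0/1 vector of per-window detections.
#' @param window_sec seconds per window.
#' @param merge_gap_sec merge runs separated by gaps up to this long
#'   (default 0: no merging).
#' @return An [interval_set()].
#' @export
#' @examples
#' detect_intervals(c(0, 1, 1, 0, 1, 0), window_sec = 1)  # [1,3), [4,5)
detect_intervals <- function(verdicts, window_sec = 1, merge_gap_sec = 0) {
  stopifnot(is_number(window_sec), window_sec > 0,
            is_number(merge_gap_sec), merge_gap_sec >= 0)
  v <- as.logical(verdicts)
  if (!length(v) || !any(v)) return(interval_set())
  r <- rle(v)
  ends_w <- cumsum(r$lengths)
  starts_w <- ends_w - r$lengths
  keep <- r$values
  out <- interval_set(starts_w[keep] * window_sec, ends_w[keep] * window_sec)
  if (merge_gap_sec > 0 && nrow(out) > 1L) {
    s <- out[, "start"]; e <- out[, "end"]
    i <- 1L
    while (i < length(s)) {
      if (s[i + 1L] - e[i] <= merge_gap_sec + 1e-9) {
        e[i] <- e[i + 1L]; s <- s[-(i + 1L)]; e <- e[-(i + 1L)]
      } else i <- i + 1L
    }
    out <- interval_set(s, e)
  }
  out
}

#' Event-level detection metrics
#'
#' A seizure (annotated event) counts as detected when any detection
#' interval intersects it; event sensitivity is detected events over total
#' events. Detection intervals intersecting no event are false positives;
#' their summed duration is scaled to minutes per hour of total recording
#' time. The onset latency of a detected event is the start of its
#' earliest intersecting detection minus the event onset, clamped at zero
#' (detections beginning early count as latency 0); missed events
#' contribute no latency.
#'
#' @param detections an [interval_set()] of detections.
#' @param seizures an [interval_set()] of annotated events, within
#'   `[0, total_duration_sec)`.
#' @param total_duration_sec total record duration in seconds.
#' @return list with `event_sensitivity` (`NA` when there are no events),
#'   `fp_duration_min_per_hr`, `latencies` (seconds, one per detected
#'   event) and `mean_latency`.
#' @export
event_metrics <- function(detections, seizures, total_duration_sec) {
  stopifnot(inherits(detections, "interval_set"),
            inherits(seizures, "interval_set"),
            is_number(total_duration_sec), total_duration_sec > 0)
  if (NROW(seizures) &&
      (any(seizures[, "start"] < 0) ||
       any(seizures[, "end"] > total_duration_sec + 1e-9))) {
    stop_edfviz("seizure intervals must lie within [0, total duration)",
                class = "edfviz_bounds_error")
  }
  hit_any <- rep(FALSE, NROW(detections))
  latencies <- numeric(0)
  detected <- 0L
  for (i in seq_len(NROW(seizures))) {
    hits <- intersects(seizures[i, ], detections)
    hit_any <- hit_any | hits
    if (any(hits)) {
      detected <- detected + 1L
      first <- min(detections[hits, "start"])
      latencies <- c(latencies, max(0, first - seizures[i, "start"]))
    }
  }
  fp_sec <- if (NROW(detections)) {
    sum((detections[, "end"] - detections[, "start"])[!hit_any])
  } else 0
  list(
    event_sensitivity = if (NROW(seizures)) detected / NROW(seizures)
                        else NA_real_,
    fp_duration_min_per_hr = (fp_sec / 60) / (total_duration_sec / 3600),
    latencies = latencies,
    mean_latency = if (length(latencies)) mean(latencies) else NA_real_
  )
}

#' Full evaluation report for one recording
#'
#' Runs the complete protocol: smooth the scores (trailing average of
#' `smooth_k` windows), calibrate the threshold on the calibration scores
#' at the false-positive budget, compute window-level metrics, merge the
#' thresholded windows into detection intervals, and compute event-level
#' metrics against the annotated seizure intervals (derived from the label
#' runs when not supplied).
#'
#' @inheritParams calibrate_threshold
#' @param calib_scores,calib_labels scores/labels used for threshold
#'   calibration (default: the evaluation scores themselves, i.e.
#'   calibrate-on-train usage passes the training stream here).
#' @param smooth_k windows averaged before thresholding (default 20);
#'   applied to calibration and evaluation scores alike.
#' @param seizures optional [interval_set()] of annotated events.
#' @param merge_gap_sec gap merged between detection runs (default 0).
#' @return An object of class `eval_report`: a list with the calibrated
#'   `threshold`, `auc_roc`, `auc_pr`, `sensitivity_window`,
#'   `specificity_window`, `event_sensitivity`, `fp_duration_min_per_hr`,
#'   `onset_latencies`, `mean_latency`, and the `detections` interval set.
#' @export
evaluate_predictions <- function(scores, labels, window_sec = 1,
                                 calib_scores = scores,
                                 calib_labels = labels,
                                 fp_budget_min_per_hr = 2, smooth_k = 20L,
                                 seizures = NULL, merge_gap_sec = 0) {
  smooth_vec <- function(x) {
    p <- prediction_set(pmin(pmax(x, 0), 1), n_samples = length(x),
                        sample_rate = 1 / window_sec)
    as.vector(smooth_predictions(p, k = smooth_k)$values)
  }
  sm_eval <- smooth_vec(scores)
  sm_cal <- smooth_vec(calib_scores)
  threshold <- calibrate_threshold(sm_cal, calib_labels, window_sec,
                                   fp_budget_min_per_hr)
  wm <- window_metrics(sm_eval, labels, threshold)
  detections <- detect_intervals(sm_eval >= threshold, window_sec,
                                 merge_gap_sec)
  if (is.null(seizures)) {
    seizures <- detect_intervals(labels == 1, window_sec)
  }
  total <- length(scores) * window_sec
  em <- event_metrics(detections, seizures, total)
  structure(
    list(threshold = threshold, auc_roc = wm$auc_roc, auc_pr = wm$auc_pr,
         sensitivity_window = wm$sensitivity,
         specificity_window = wm$specificity,
         event_sensitivity = em$event_sensitivity,
         fp_duration_min_per_hr = em$fp_duration_min_per_hr,
         onset_latencies = em$latencies, mean_latency = em$mean_latency,
         detections = detections, window_sec = window_sec,
         smooth_k = smooth_k, fp_budget_min_per_hr = fp_budget_min_per_hr),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> threshold ", num_str(x$threshold, 4),
      " (budget ", num_str(x$fp_budget_min_per_hr), " min FP/hr, smooth k=",
      x$smooth_k, ")\n", sep = "")
  cat(sprintf("  window level: AUC-ROC %.3f  AUC-PR %.3f  sens %.3f  spec %.3f\n",
              x$auc_roc, x$auc_pr, x$sensitivity_window,
              x$specificity_window))
  cat(sprintf("  event level:  sensitivity %.3f  FP %.3f min/hr  mean latency %s s\n",
              x$event_sensitivity, x$fp_duration_min_per_hr,
              if (is.na(x$mean_latency)) "NA" else num_str(x$mean_latency, 4)))
  cat("  detections: ", NROW(x$detections), " interval(s)\n", sep = "")
  invisible(x)
}

#' Aggregate per-recording reports across patients
#'
#' First averages each metric across all recordings (seizure bouts) of a
#' patient, then summarises the per-patient means across patients with the
#' box-plot statistics: median, inter-quartile range, and the 10th/90th
#' percentiles.
#'
#' @param reports a list of [evaluate_predictions()] reports, or a data
#'   frame with one row per recording and one column per metric.
#' @param patient_ids vector assigning each report to a patient.
#' @return list with `per_patient` (data frame of per-patient means) and
#'   `summary` (data frame: one row per metric with `median`, `q25`,
#'   `q75`, `p10`, `p90`).
#' @export
aggregate_per_patient <- function(reports, patient_ids) {
  metrics <- c("auc_roc", "auc_pr", "sensitivity_window",
               "specificity_window", "event_sensitivity",
               "fp_duration_min_per_hr", "mean_latency")
  if (is.data.frame(reports)) {
    df <- reports
    metrics <- intersect(metrics, names(df))
    if (!length(metrics)) metrics <- names(df)[vapply(df, is.numeric, TRUE)]
  } else {
    df <- do.call(rbind, lapply(reports, function(r) {
      as.data.frame(r[metrics])
    }))
  }
  stopifnot(length(patient_ids) == nrow(df))
  per_patient <- stats::aggregate(df[metrics], list(patient = patient_ids),
                                  mean, na.rm = TRUE)
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_patient[[m]]
    q <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), na.rm = TRUE, names = FALSE)
    data.frame(metric = m, median = q[3L], q25 = q[2L], q75 = q[4L],
               p10 = q[1L], p90 = q[5L])
  }))
  rownames(summ) <- NULL
  list(per_patient = per_patient, summary = summ)
}
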