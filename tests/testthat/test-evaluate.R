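# Threshold calibration, window- and event-level metrics, aggregation.

test_that("calibrate_threshold picks the smallest budget-feasible candidate", {
  # all-zero scores on a mixed stream: threshold 0 marks every baseline
  # window positive (rule is score >= t), so the only feasible candidate
  # is the appended 1.0
  expect_equal(calibrate_threshold(numeric(100), rep(c(0, 1), 50)), 1)

  # perfect scores: candidates {0, 1}; 0 floods baseline, 1 gives FP 0
  labels <- rep(c(0, 1), each = 50)
  expect_equal(calibrate_threshold(labels, labels), 1)
  wm <- window_metrics(labels, labels, 1)
  expect_equal(wm$sensitivity, 1)

  # graded scores: returned threshold is the smallest whose recounted FP
  # time per baseline hour is within budget, and candidates below it fail
  withr::with_seed(1, {
    scores <- stats::rbeta(7200, 1, 8)
    labels <- rep(0, 7200)
  })
  th <- calibrate_threshold(scores, labels, window_sec = 1,
                            fp_budget_min_per_hr = 2)
  fp_rate <- function(t) {
    sum(labels == 0 & scores >= t) / 60 / (sum(labels == 0) / 3600)
  }
  expect_lte(fp_rate(th), 2)
  below <- max(scores[scores < th])
  expect_gt(fp_rate(below), 2)
})

test_that("calibration is monotone in the budget", {
  withr::with_seed(2, {
    scores <- pmin(pmax(rep(c(0, 1), each = 600) + rnorm(1200, 0, 0.3), 0), 1)
    labels <- rep(c(0, 1), each = 600)
  })
  budgets <- c(0.5, 1, 2, 5, 10, 30)
  ths <- vapply(budgets, function(b) {
    calibrate_threshold(scores, labels, fp_budget_min_per_hr = b)
  }, numeric(1))
  expect_true(all(diff(ths) <= 0))  # larger budget, never larger threshold
})

test_that("AUC-ROC equals the all-pairs Mann-Whitney oracle", {
  wm <- window_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), 0.5)
  expect_equal(wm$auc_roc, 0.75)

  withr::with_seed(3, {
    scores <- round(runif(400), 2)  # many ties
    labels <- rbinom(400, 1, 0.3)
  })
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  expect_equal(window_metrics(scores, labels, 0.5)$auc_roc,
               wins / (length(pos) * length(neg)))
})

test_that("AUCs agree with pROC on a tied score stream", {
  skip_if_not_installed("pROC")
  withr::with_seed(4, {
    scores <- round(runif(300), 2)
    labels <- rbinom(300, 1, 0.4)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(window_metrics(scores, labels, 0.5)$auc_roc, ref,
               tolerance = 1e-12)
})

test_that("perfect and null scores bracket the AUCs", {
  labels <- rep(c(0, 1), each = 100)
  wm <- window_metrics(labels, labels, 0.5)
  expect_equal(wm$auc_roc, 1)
  expect_equal(wm$auc_pr, 1)

  withr::with_seed(5, {
    scores <- runif(10000)
    labels <- sample(rep(c(0, 1), each = 5000))
  })
  expect_lt(abs(window_metrics(scores, labels, 0.5)$auc_roc - 0.5), 0.02)

  one_class <- window_metrics(runif(10), rep(1, 10), 0.5)
  expect_true(is.na(one_class$auc_roc))
  expect_true(is.na(one_class$specificity))
  expect_false(is.na(one_class$sensitivity))
})

test_that("detect_intervals merges runs by the gap rule", {
  iv <- detect_intervals(c(0, 1, 1, 0, 1, 0), window_sec = 1)
  expect_equal(unclass(iv), cbind(start = c(1, 4), end = c(3, 5)),
               ignore_attr = TRUE)

  expect_equal(NROW(detect_intervals(rep(0, 10), 1)), 0L)

  gappy <- c(1, 0, 1, 0, 0, 1)
  merged <- detect_intervals(gappy, window_sec = 1, merge_gap_sec = 1)
  expect_equal(unclass(merged), cbind(start = c(0, 5), end = c(3, 6)),
               ignore_attr = TRUE)
  expect_equal(NROW(detect_intervals(gappy, 1, merge_gap_sec = 2)), 1L)
})

test_that("event metrics apply the intersection definitions", {
  em <- event_metrics(interval_set(c(110, 200), c(130, 210)),
                      interval_set(100, 160), 3600)
  expect_equal(em$event_sensitivity, 1)
  expect_equal(em$fp_duration_min_per_hr, 10 / 60)
  expect_equal(em$latencies, 10)

  none <- event_metrics(interval_set(), interval_set(100, 160), 3600)
  expect_equal(none$event_sensitivity, 0)
  expect_equal(none$fp_duration_min_per_hr, 0)
  expect_length(none$latencies, 0)

  # a wall-to-wall detection intersects the seizure: no FP time at all
  wall <- event_metrics(interval_set(0, 3600), interval_set(100, 160), 3600)
  expect_equal(wall$event_sensitivity, 1)
  expect_equal(wall$latencies, 0)     # clamped, not negative
  expect_equal(wall$fp_duration_min_per_hr, 0)

  no_sz <- event_metrics(interval_set(0, 10), interval_set(), 3600)
  expect_true(is.na(no_sz$event_sensitivity))
  expect_equal(no_sz$fp_duration_min_per_hr, 10 / 60)
})

test_that("splitting a detection inside a seizure changes nothing", {
  seiz <- interval_set(100, 160)
  whole <- event_metrics(interval_set(90, 170), seiz, 3600)
  split <- event_metrics(interval_set(c(90, 120), c(120, 170)), seiz, 3600)
  expect_equal(split$event_sensitivity, whole$event_sensitivity)
  expect_equal(split$fp_duration_min_per_hr, whole$fp_duration_min_per_hr)
})

test_that("interval sets normalise to sorted disjoint intervals", {
  iv <- interval_set(c(5, 1, 2), c(6, 2.5, 3))
  expect_equal(unclass(iv), cbind(start = c(1, 5), end = c(3, 6)),
               ignore_attr = TRUE)
  expect_error(interval_set(3, 3), class = "edfviz_validation_error")
})

test_that("per-patient aggregation reproduces the box-plot statistics", {
  one <- data.frame(event_sensitivity = 0.8, auc_roc = 0.9)
  agg1 <- aggregate_per_patient(one, patient_ids = "p1")
  expect_equal(agg1$summary$median,
               unname(unlist(one[c("auc_roc", "event_sensitivity")])),
               tolerance = 1e-12)

  two <- data.frame(event_sensitivity = c(1, 1, 0))
  agg2 <- aggregate_per_patient(two, patient_ids = c("a", "a", "b"))
  expect_equal(agg2$summary$median, 0.5)

  withr::with_seed(6, {
    vals <- runif(48)
    ids <- rep(sprintf("p%02d", 1:16), each = 3)
  })
  df <- data.frame(auc_roc = vals)
  agg <- aggregate_per_patient(df, ids)
  means <- tapply(vals, ids, mean)  # brute-force per-patient means
  expect_equal(agg$per_patient$auc_roc,
               as.numeric(means[agg$per_patient$patient]))
  expect_equal(agg$summary[agg$summary$metric == "auc_roc",
                           c("p10", "q25", "median", "q75", "p90")],
               as.data.frame(as.list(stats::setNames(
                 quantile(means, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE),
                 c("p10", "q25", "median", "q75", "p90")))),
               ignore_attr = TRUE)
})

test_that("evaluate_predictions assembles a coherent report", {
  lab <- window_labels(interval_set(c(300, 1200), c(360, 1290)), 3600)
  s <- synth_scores(lab, quality_sd = 0.1, seed = 8)
  rep <- evaluate_predictions(s$scores, s$labels)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$event_sensitivity, 1)
  expect_lte(rep$fp_duration_min_per_hr, 2)
  expect_gt(rep$auc_roc, 0.95)
  expect_true(all(rep$onset_latencies >= 0))
  expect_output(print(rep), "event level")
})
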