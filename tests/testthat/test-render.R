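# Rendering contracts: trace shading geometry, electrode layout, and the
# exactness of the scalp interpolation. Pixel contents are not inspected;
# the drawing hooks return the geometry that was drawn.

test_that("render_traces writes a PNG with the contracted pixel size", {
  rec <- synth_recording(synth_spec(duration_sec = 10, seed = 1))
  d <- apply_montage(rec, builtin_montage("ten_twenty"))
  f <- withr::local_tempfile(fileext = ".png")
  cfg <- render_config(dpi = 72, title = "Patient 1")
  out <- render_traces(d, cfg, file = f)
  expect_true(file.exists(f))
  png_dims <- function(p) {
    raw <- readBin(p, "raw", 32L)
    c(sum(as.integer(raw[17:20]) * 256^(3:0)),
      sum(as.integer(raw[21:24]) * 256^(3:0)))
  }
  expect_equal(png_dims(f), c(8 * 72, round((1 + 0.45 * 19) * 72)))
  expect_equal(names(out$spans), d$names)
})

test_that("shaded spans match the detection intervals one to one", {
  rec <- synth_recording(synth_spec(duration_sec = 20, seed = 2))
  d <- apply_montage(rec, builtin_montage("ten_twenty"))
  verdicts <- rep(0, 20); verdicts[c(3:5, 12:13)] <- 1  # 2 detection runs
  p <- prediction_set(verdicts, n_samples = 4000, sample_rate = 200)
  mask <- to_sample_mask(p, 0.5)
  f <- withr::local_tempfile(fileext = ".png")
  out <- render_traces(d, render_config(window_sec = 20), mask = mask,
                       annotations = rec$annotations, file = f)
  n_intervals <- NROW(detect_intervals(verdicts, 1))
  for (ch in names(out$spans)) {
    expect_length(out$spans[[ch]], n_intervals)  # subject mask: all channels
  }
  expect_equal(out$spans[[1]][[1]], c(2, 5))
  expect_equal(out$spans[[1]][[2]], c(11, 13))
})

test_that("mask/sample misalignment is rejected", {
  rec <- synth_recording(synth_spec(duration_sec = 10, seed = 3))
  d <- apply_montage(rec, builtin_montage("ten_twenty"))
  p <- prediction_set(runif(5), n_samples = 1000, sample_rate = 200)
  expect_error(render_traces(d, render_config(), mask = to_sample_mask(p)),
               class = "edfviz_alignment_error")
})

test_that("electrode layout matches the 10-20 geometry", {
  pos <- electrode_positions(c("CZ", "C3", "C4", "O1", "FP1", "T3"))
  expect_equal(unname(pos["CZ", ]), c(0, 0))
  expect_equal(pos["C3", "y"], pos["C4", "y"])
  expect_equal(pos["C3", "x"], -pos["C4", "x"])     # mirror pair
  expect_lt(pos["O1", "y"], pos["FP1", "y"])        # posterior below anterior
  expect_true(all(rowSums(pos^2) <= 1 + 1e-4))      # inside the head disk
  expect_equal(unname(pos["T3", ]), c(-1, 0), tolerance = 1e-9)

  expect_error(electrode_positions("NOPE"), "known",
               class = "edfviz_lookup_error")
})

test_that("scalp interpolation is exact at electrodes and on constants", {
  labels <- builtin_montage("ten_twenty")$derivations$name
  pos <- electrode_positions(labels)
  vals <- withr::with_seed(4, runif(19))

  interp <- topo_interpolate(vals, pos, grid_n = 65)
  # constant input -> constant field
  flat <- topo_interpolate(rep(2.5, 19), pos, grid_n = 33)
  expect_lt(max(abs(flat$field - 2.5), na.rm = TRUE), 1e-9)

  # the interpolant passes through every electrode value
  tps <- function(d) ifelse(d > 0, d^2 * log(d), 0)
  K <- tps(as.matrix(stats::dist(pos)))
  P <- cbind(1, pos)
  coef <- solve(rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3))),
                c(vals, numeric(3)))
  at_electrode <- vapply(seq_len(19), function(i) {
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    sum(coef[1:19] * tps(d)) + coef[20] + sum(coef[21:22] * pos[i, ])
  }, numeric(1))
  expect_lt(max(abs(at_electrode - vals)), 1e-6)

  # a lone hot electrode produces the field maximum at its position
  hot <- as.numeric(labels == "C3")
  hi <- topo_interpolate(hot, pos, grid_n = 129)
  ix <- which(hi$field == max(hi$field, na.rm = TRUE), arr.ind = TRUE)
  peak <- c(hi$x[ix[1, 1]], hi$y[ix[1, 2]])
  expect_lt(sqrt(sum((peak - pos["C3", ])^2)), 0.1)

  expect_error(topo_interpolate(1:3, pos[1:3, ]),
               class = "edfviz_validation_error")
  expect_error(topo_interpolate(c(1, NA, 3, 4), pos[1:4, ]),
               class = "edfviz_validation_error")
})

test_that("render_topoplot writes an image and returns the field", {
  vals <- stats::setNames(runif(19), builtin_montage("ten_twenty")$derivations$name)
  f <- withr::local_tempfile(fileext = ".png")
  out <- render_topoplot(vals, time_label = "t = 12 s", file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
  expect_true(all(is.na(out$field[outer(out$x^2, out$y^2, `+`) > 1])))
})

test_that("the drawn geometry is a pure function of its inputs", {
  rec <- synth_recording(synth_spec(duration_sec = 5, seed = 5))
  d <- apply_montage(rec, builtin_montage("ten_twenty"))
  p <- prediction_set(c(0, 1, 0, 1, 1), n_samples = 1000, sample_rate = 200)
  mask <- to_sample_mask(p, 0.5)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  s1 <- render_traces(d, render_config(), mask = mask, file = f1)$spans
  s2 <- render_traces(d, render_config(), mask = mask, file = f2)$spans
  expect_identical(s1, s2)
})
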