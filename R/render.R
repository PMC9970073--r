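# Static rendering: stacked traces with prediction shading and annotation
# row, and topographic scalp maps. PNG output via grDevices; drawing
# geometry (shaded spans, interpolated field) is returned invisibly so
# tests can assert on it without decoding pixels.

HEMISPHERE_COLORS <- c(left = "red3", right = "blue3", midline = "green4",
                       unknown = "gray35")
OVERLAY_COLOR <- grDevices::rgb(0.70, 0.95, 0.96, alpha = 0.55)  # light cyan

#' Rendering configuration for trace plots
#'
#' @param window_sec seconds of signal shown per screen width; the GUI
#'   presets are 1, 5, 10, 20, 25, 30 or 45 s but any positive value is
#'   accepted (default 10).
#' @param amplitude_scale microvolts spanned by one trace slot
#'   (default 200).
#' @param title plot title.
#' @param line_width trace line width (default 0.6).
#' @param font_size base font size in points (default 10).
#' @param dpi raster resolution (default 120).
#' @param show_annotations draw the bottom "Notes" row (default TRUE).
#' @param onset_marker_sec optional time of a dashed vertical marker
#'   (e.g. annotated seizure onset).
#' @return list of class `render_config`.
#' @export
render_config <- function(window_sec = 10, amplitude_scale = 200,
                          title = "", line_width = 0.6, font_size = 10,
                          dpi = 120, show_annotations = TRUE,
                          onset_marker_sec = NULL) {
  stopifnot(is_number(window_sec), window_sec > 0,
            is_number(amplitude_scale), amplitude_scale > 0,
            is_number(line_width), line_width > 0,
            is_number(font_size), font_size > 0,
            is_count(dpi))
  structure(
    list(window_sec = window_sec, amplitude_scale = amplitude_scale,
         title = title, line_width = line_width, font_size = font_size,
         dpi = dpi, show_annotations = isTRUE(show_annotations),
         onset_marker_sec = onset_marker_sec),
    class = "render_config"
  )
}

#' Render stacked EEG traces with prediction shading
#'
#' Draws the derived channels top-to-bottom in montage order, coloured by
#' hemisphere (red left, blue right, green midline, grey unknown). Samples
#' where the mask is true are shaded in light cyan behind the affected
#' channel; a subject-scope (single row) mask shades all channels.
#' Annotations appear in a bottom "Notes" row, and an optional dashed
#' vertical line marks a given onset time.
#'
#' @param derived a `derived_channels` object from [apply_montage()].
#' @param config a [render_config()].
#' @param mask optional `sample_mask` from [to_sample_mask()]; its sample
#'   length must match the channels.
#' @param annotations optional annotation data frame
#'   (`onset`, `duration`, `text`).
#' @param file output PNG path.
#' @param start_sec time of the first sample on the recording clock, used
#'   only for axis labelling (default 0).
#' @return Invisibly, a list with `file` and `spans` — per channel, the
#'   list of shaded `[start_sec, end_sec)` spans actually drawn (the test
#'   hook).
#' @export
render_traces <- function(derived, config = render_config(), mask = NULL,
                          annotations = NULL, file = tempfile(fileext = ".png"),
                          start_sec = 0) {
  stopifnot(inherits(derived, "derived_channels"),
            inherits(config, "render_config"))
  nch <- length(derived$names)
  if (nch < 1L) {
    stop_edfviz("need at least one channel to render",
                class = "edfviz_validation_error")
  }
  n <- length(derived$samples[[1L]])
  if (!is.null(mask)) {
    if (ncol(mask) != n) {
      stop_edfviz("mask has ", ncol(mask), " samples but channels have ", n,
                  class = "edfviz_alignment_error")
    }
    if (nrow(mask) != 1L && nrow(mask) != nch) {
      stop_edfviz("mask has ", nrow(mask), " rows; expected 1 or ", nch,
                  class = "edfviz_alignment_error")
    }
  }
  dur <- n / derived$sample_rates[1L]
  notes_rows <- if (config$show_annotations && NROW(annotations)) 1L else 0L
  width_px <- as.integer(round(8 * config$dpi))
  height_px <- as.integer(round((1 + 0.45 * (nch + notes_rows)) * config$dpi))

  grDevices::png(file, width = width_px, height = height_px,
                 res = config$dpi)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(2.5, 5, if (nzchar(config$title)) 2.2 else 0.6,
                              0.6),
                      ps = config$font_size)
  on.exit(graphics::par(op), add = TRUE, after = FALSE)

  ylim <- c(-(nch + notes_rows) - 0.5, -0.5)
  graphics::plot(NA, xlim = c(start_sec, start_sec + dur), ylim = ylim,
                 xlab = "", ylab = "", yaxt = "n", bty = "n",
                 main = config$title, xaxs = "i")
  graphics::axis(2, at = -seq_len(nch), labels = derived$names, las = 1,
                 tick = FALSE)

  spans <- rep(list(list()), nch)
  names(spans) <- derived$names
  for (j in seq_len(nch)) {
    x <- derived$samples[[j]]
    r <- derived$sample_rates[j]
    tt <- start_sec + (seq_along(x) - 1L) / r
    y0 <- -j
    if (!is.null(mask)) {
      row <- if (nrow(mask) == 1L) mask[1L, ] else mask[j, ]
      runs <- rle(as.logical(row))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths
      for (k in which(runs$values)) {
        s0 <- start_sec + starts[k] / r
        s1 <- start_sec + ends[k] / r
        graphics::rect(s0, y0 - 0.45, s1, y0 + 0.45,
                       col = OVERLAY_COLOR, border = NA)
        spans[[j]] <- c(spans[[j]], list(c(s0, s1)))
      }
    }
    graphics::lines(tt, y0 + x / config$amplitude_scale,
                    col = HEMISPHERE_COLORS[[derived$hemispheres[j]]],
                    lwd = config$line_width)
  }
  if (notes_rows) {
    y0 <- -(nch + 1L)
    graphics::axis(2, at = y0, labels = "Notes", las = 1, tick = FALSE)
    keep <- annotations$onset >= start_sec - 1e-9 &
      annotations$onset < start_sec + dur
    ann <- annotations[keep, , drop = FALSE]
    for (i in seq_len(nrow(ann))) {
      graphics::segments(ann$onset[i], y0 - 0.4, ann$onset[i], y0 + 0.4,
                         col = "gray40")
      graphics::text(ann$onset[i], y0, labels = ann$text[i], pos = 4,
                     cex = 0.8, col = "gray20")
    }
  }
  if (!is.null(config$onset_marker_sec)) {
    graphics::abline(v = config$onset_marker_sec, lty = "dashed",
                     col = "black")
  }
  invisible(list(file = file, spans = spans))
}

#' Projected 2-D positions of standard scalp electrodes
#'
#' Looks labels up in the shipped coordinate table
#' (`inst/extdata/electrode_positions.tsv`): azimuthal-equidistant
#' projections of the standard 10-20/10-10 placements onto the unit head
#' disk, Cz at the origin, front at +y, right at +x. The table is plain
#' text and can be extended by users with non-standard electrodes.
#'
#' @param labels character vector of electrode labels (matched after the
#'   same normalisation as [apply_montage()]).
#' @return numeric matrix with columns `x`, `y` and one named row per
#'   label.
#' @section Errors: unknown electrodes raise a lookup error listing the
#'   known labels.
#' @export
#' @examples
#' electrode_positions(c("CZ", "C3", "C4"))
electrode_positions <- function(labels) {
  tab <- utils::read.table(
    system.file("extdata", "electrode_positions.tsv", package = "edfviz",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE
  )
  want <- normalize_electrode(labels)
  hit <- match(want, tab$label)
  if (anyNA(hit)) {
    stop_edfviz("unknown electrode(s): ",
                paste(labels[is.na(hit)], collapse = ", "),
                "; known: ", paste(tab$label, collapse = ", "),
                class = "edfviz_lookup_error")
  }
  out <- as.matrix(tab[hit, c("x", "y")])
  rownames(out) <- labels
  out
}

#' Thin-plate-spline interpolation of electrode values over the scalp
#'
#' Fits the exact thin-plate interpolant (radial basis `r^2 log r` plus an
#' affine term) through the electrode values and evaluates it on a square
#' grid over `[-1, 1]^2`, masked to the unit head disk. Constant inputs
#' yield a constant field; the field equals the inputs at the electrode
#' positions.
#'
#' @param values numeric vector, one value per electrode (at least 4).
#' @param positions matrix of electrode `x`, `y` positions (e.g. from
#'   [electrode_positions()]).
#' @param grid_n grid resolution per axis (default 64).
#' @return list with `x`, `y` (grid axes) and `field` (`grid_n` x `grid_n`
#'   matrix, `NA` outside the head disk).
#' @export
topo_interpolate <- function(values, positions, grid_n = 64L) {
  stopifnot(is.numeric(values), is.matrix(positions),
            nrow(positions) == length(values), is_count(grid_n))
  if (length(values) < 4L) {
    stop_edfviz("scalp interpolation needs at least 4 electrodes",
                class = "edfviz_validation_error")
  }
  if (any(!is.finite(values))) {
    stop_edfviz("electrode values must be finite",
                class = "edfviz_validation_error")
  }
  p <- length(values)
  tps_kernel <- function(d) ifelse(d > 0, d^2 * log(d), 0)
  D <- as.matrix(stats::dist(positions))
  K <- tps_kernel(D)
  P <- cbind(1, positions)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  coef <- solve(A, c(values, numeric(3L)))
  w <- coef[seq_len(p)]
  a <- coef[p + 1:3]
  ax <- seq(-1, 1, length.out = grid_n)
  grid <- as.matrix(expand.grid(x = ax, y = ax))
  d2 <- outer(grid[, 1L], positions[, 1L], `-`)^2 +
    outer(grid[, 2L], positions[, 2L], `-`)^2
  vals <- tps_kernel(sqrt(d2)) %*% w + a[1L] + grid %*% a[2:3]
  field <- matrix(vals, grid_n, grid_n)  # rows: x, cols: y
  outside <- matrix(grid[, 1L]^2 + grid[, 2L]^2 > 1, grid_n, grid_n)
  field[outside] <- NA_real_
  list(x = ax, y = ax, field = field)
}

#' Render a topographic scalp map
#'
#' Interpolates per-electrode values over the head disk with
#' [topo_interpolate()], draws the field with a head/nose outline and
#' electrode dots, and writes a PNG. The subplot title defaults to the
#' time label.
#'
#' @param channel_values named numeric vector: electrode label -> value.
#' @param positions optional position matrix; defaults to
#'   [electrode_positions()] of the value names.
#' @param time_label optional label (e.g. `"t = 12 s"`), used as title.
#' @param file output PNG path.
#' @param grid_n interpolation grid resolution (default 64).
#' @param dpi raster resolution (default 120).
#' @return Invisibly, a list with `file` and the interpolation result
#'   (`x`, `y`, `field`).
#' @export
render_topoplot <- function(channel_values, positions = NULL,
                            time_label = NULL,
                            file = tempfile(fileext = ".png"),
                            grid_n = 64L, dpi = 120L) {
  stopifnot(is.numeric(channel_values))
  if (is.null(positions)) {
    if (is.null(names(channel_values))) {
      stop_edfviz("`channel_values` must be named by electrode when no ",
                  "positions are given", class = "edfviz_validation_error")
    }
    positions <- electrode_positions(names(channel_values))
  }
  interp <- topo_interpolate(channel_values, positions, grid_n)

  grDevices::png(file, width = 4 * dpi, height = 4 * dpi, res = dpi)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(0.5, 0.5, if (is.null(time_label)) 0.5 else 2, 0.5))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  pal <- grDevices::hcl.colors(64L, "Viridis")
  graphics::image(interp$x, interp$y, interp$field, col = pal, asp = 1,
                  xlab = "", ylab = "", axes = FALSE,
                  main = if (is.null(time_label)) "" else time_label,
                  xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25))
  th <- seq(0, 2 * pi, length.out = 181L)
  graphics::lines(cos(th), sin(th), lwd = 2)                       # head
  graphics::lines(c(-0.1, 0, 0.1), c(0.995, 1.1, 0.995), lwd = 2)  # nose
  graphics::points(positions[, 1L], positions[, 2L], pch = 16, cex = 0.5)
  invisible(list(file = file, x = interp$x, y = interp$y,
                 field = interp$field))
}
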