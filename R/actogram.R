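#' Render an actogram
#'
#' Day-per-row raster of activity counts, optionally double-plotted (each row
#' shows 48 h: day d followed by day d+1), with the scheduled light phase
#' shaded. Purely presentational; DD days get no shading, LL days are fully
#' shaded.
#'
#' @param series an [activity_series()] spanning at least one day.
#' @param schedule optional [light_schedule()] used for shading.
#' @param double_plot logical; draw 48-h rows.
#' @param file optional output path (`.png` or `.svg`); if `NULL`, draws on
#'   the current device.
#' @param width,height device size in pixels (png) or inches (svg).
#' @param ... passed to the device function.
#' @return The output path (or `NULL`), invisibly.
#' @export
render_actogram <- function(series, schedule = NULL, double_plot = TRUE,
                            file = NULL, width = 800, height = 600, ...) {
  dm <- fold_daily(series, 24)
  n_days <- nrow(dm$mat)
  if (n_days < 1L) stop("series must span at least one day")
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, ...)
    else grDevices::png(file, width = width, height = height, ...)
    on.exit(grDevices::dev.off())
  }
  bins <- ncol(dm$mat)
  span_h <- if (double_plot) 48 else 24
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NULL, xlim = c(0, span_h), ylim = c(n_days, 0),
                 xlab = "time of day (h)", ylab = "day", xaxt = "n",
                 main = series$subject_id)
  graphics::axis(1, at = seq(0, span_h, by = 6))
  shade_day <- function(d, x_off, y0, y1) {
    if (is.null(schedule) || d > last_day(schedule)) return()
    info <- day_info(schedule, d)
    if (info$photoperiod_h <= 0) return()
    on <- info$lights_on; off <- on + info$photoperiod_h
    seg <- if (off <= 24) list(c(on, off)) else list(c(on, 24), c(0, off - 24))
    for (sg in seg)
      graphics::rect(x_off + sg[1], y0, x_off + sg[2], y1,
                     col = grDevices::adjustcolor("gold", 0.3), border = NA)
  }
  peak <- max(dm$mat, 1)
  for (d in seq_len(n_days)) {
    y0 <- d - 1; y1 <- d
    shade_day(d - 1, 0, y0, y1)
    if (double_plot && d < n_days) shade_day(d, 24, y0, y1)
    draw_row <- function(row, x_off) {
      h <- row / peak * 0.9
      x <- x_off + (seq_len(bins) - 1) / bins * 24
      graphics::rect(x[h > 0], y1 - h[h > 0], (x + 24 / bins)[h > 0], y1,
                     col = "black", border = NA)
    }
    draw_row(dm$mat[d, ], 0)
    if (double_plot && d < n_days) draw_row(dm$mat[d + 1, ], 24)
  }
  invisible(file)
}

#' @export
plot.activity_series <- function(x, schedule = NULL, double_plot = TRUE, ...) {
  render_actogram(x, schedule = schedule, double_plot = double_plot, ...)
}
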