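# Visual outputs: red/cyan stereo anaglyph and simple report plots.
# The anaglyph composes the raw views directly (red = left, cyan = right),
# the conventional rendering for human stereo viewing of a parallax pair.

#' Red/cyan anaglyph of a stereo pair
#'
#' Red channel = left view, green and blue = right view, each normalised to
#' its own 99.9th percentile (robust against hot pixels) and clipped to
#' `[0, 1]`.
#'
#' @param pair A `stereo_pair`.
#' @return `height x width x 3` numeric array in `[0, 1]`.
#' @export
anaglyph_array <- function(pair) {
  norm01 <- function(m) {
    hi <- stats::quantile(m, 0.999, names = FALSE)
    if (hi <= 0) hi <- 1
    pmin(pmax(m / hi, 0), 1)
  }
  arr <- array(0, dim = c(dim(pair$left), 3L))
  arr[, , 1] <- norm01(pair$left)
  arr[, , 2] <- norm01(pair$right)
  arr[, , 3] <- arr[, , 2]
  arr
}

#' Write a stereo pair as a red/cyan anaglyph PNG
#' @param pair A `stereo_pair`.
#' @param path Output PNG path.
#' @return The path, invisibly; errors if the `png` package is unavailable.
#' @export
write_anaglyph_png <- function(pair, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("writing PNG anaglyphs requires the 'png' package")
  png::writePNG(anaglyph_array(pair), path)
  invisible(path)
}

# device plot helper: never let a headless device failure kill a pipeline
safe_png_plot <- function(path, width, height, draw) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
    TRUE
  }, error = function(e) {
    warning("could not render ", path, ": ", conditionMessage(e))
    FALSE
  })
  invisible(ok)
}

#' Plot an MSD curve to PNG
#' @param msd An `msd_curve` (or a table of several with a `track_id`
#'   column, plotted as grey lines with the mean overlaid).
#' @param path Output PNG path.
#' @return Invisibly, whether the plot was written.
#' @export
plot_msd_png <- function(msd, path) {
  safe_png_plot(path, 640, 480, function() {
    if (!is.null(msd$track_id)) {
      sp <- split(msd, msd$track_id)
      plot(NA, xlim = range(msd$lag_s), ylim = range(msd$msd_um2),
           xlab = "lag (s)", ylab = "MSD (um^2)", main = "Mean squared displacement")
      for (m in sp) graphics::lines(m$lag_s, m$msd_um2, col = "grey70")
      avg <- stats::aggregate(msd_um2 ~ lag_s, msd, mean)
      graphics::lines(avg$lag_s, avg$msd_um2, lwd = 2)
    } else {
      plot(msd$lag_s, msd$msd_um2, type = "b", xlab = "lag (s)",
           ylab = "MSD (um^2)", main = "Mean squared displacement")
    }
  })
}

#' Plot a depth-error histogram to PNG
#' @param report A `depth_error_report`.
#' @param path Output PNG path.
#' @return Invisibly, whether the plot was written.
#' @export
plot_depth_error_png <- function(report, path) {
  safe_png_plot(path, 640, 480, function() {
    graphics::hist(report$errors_um, breaks = 10, col = "grey80",
                   xlab = "|depth error| (um)", main = "Depth error")
    graphics::abline(v = report$mean_um, lwd = 2, col = "red")
  })
}
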