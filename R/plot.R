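#' Plot an aligned population growth-rate curve
#'
#' Mean growth rate per cell-cycle-unit bin with the bootstrap confidence
#' band drawn as a shaded polygon.
#'
#' @param x An `aligned_population`.
#' @param col Curve colour.
#' @param add Add to an existing plot.
#' @param ... Passed to `plot()`.
#' @return `x`, invisibly.
#' @export
plot.aligned_population <- function(x, col = "#1b9e77", add = FALSE, ...) {
  ok <- !is.na(x$mean_rate)
  if (!add) {
    ylim <- range(c(x$ci_low, x$ci_high, x$mean_rate), na.rm = TRUE)
    plot(NA, xlim = c(0, 1), ylim = ylim,
         xlab = "cell cycle units", ylab = "growth rate (min^-1)", ...)
  }
  band <- ok & !is.na(x$ci_low)
  if (any(band)) {
    bc <- x$bin_centers[band]
    graphics::polygon(c(bc, rev(bc)),
                      c(x$ci_low[band], rev(x$ci_high[band])),
                      col = grDevices::adjustcolor(col, alpha.f = 0.25),
                      border = NA)
  }
  graphics::lines(x$bin_centers[ok], x$mean_rate[ok], col = col, lwd = 2)
  invisible(x)
}

#' Plot a tempogram
#'
#' Heatmap of per-cell growth-rate rows (sorted by interdivision time, the
#' shortest cycle at the top) against cell-cycle units.
#'
#' @param x A `tempogram` matrix.
#' @param ... Passed to `image()`.
#' @return `x`, invisibly.
#' @export
plot.tempogram <- function(x, ...) {
  m <- unclass(x)
  attr(m, "interdivision_time") <- NULL
  # flip rows so the shortest interdivision time renders at the top
  graphics::image(x = (seq_len(ncol(m)) - 0.5) / ncol(m),
                  y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE),
                  xlab = "cell cycle units", ylab = "cell (sorted)", ...)
  invisible(x)
}
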