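#' Raster plot of network spiking activity
#'
#' Spike times per neuron, excitatory layer below, inhibitory above the
#' dashed separator. Presentation only; no analysis depends on it.
#'
#' @param raster An `"fhn_raster"` object.
#' @param N_E Number of excitatory neurons (drawn first).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_raster <- function(raster, N_E = length(raster), ...) {
  tr <- attr(raster, "t_range")
  graphics::plot(NA, xlim = tr, ylim = c(0, length(raster) + 1),
                 xlab = "time", ylab = "neuron index", ...)
  for (i in seq_along(raster)) {
    if (length(raster[[i]])) {
      graphics::points(raster[[i]], rep(i, length(raster[[i]])),
                       pch = "|", cex = 0.4,
                       col = if (i <= N_E) "black" else "blue")
    }
  }
  if (N_E < length(raster)) graphics::abline(h = N_E + 0.5, lty = 2)
  invisible(NULL)
}

#' Resonance curve from a one-dimensional sweep
#'
#' Mean correlation time against the swept parameter with +/- 1 standard
#' error bars.
#'
#' @param result An `"fhn_sweep_result"`.
#' @param swept Swept parameter column.
#' @param response,se Response and standard-error columns.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_resonance <- function(result, swept, response = "T_bar",
                           se = "T_bar_se", ...) {
  x <- result[[swept]]; y <- result[[response]]; s <- result[[se]]
  o <- order(x)
  graphics::plot(x[o], y[o], type = "b", pch = 19,
                 xlab = swept, ylab = "mean correlation time", ...)
  graphics::arrows(x[o], y[o] - s[o], x[o], y[o] + s[o],
                   angle = 90, code = 3, length = 0.03)
  invisible(NULL)
}

#' Two-parameter contour of sweep results
#'
#' Filled contour of the mean correlation time over a two-dimensional grid.
#'
#' @param result An `"fhn_sweep_result"` over exactly two swept parameters.
#' @param x_par,y_par Names of the swept parameter columns.
#' @param response Response column.
#' @param ... Passed to [graphics::filled.contour()].
#' @return Invisibly, `NULL`.
#' @export
plot_contour <- function(result, x_par, y_par, response = "T_bar", ...) {
  xs <- sort(unique(result[[x_par]]))
  ys <- sort(unique(result[[y_par]]))
  z <- matrix(NA_real_, length(xs), length(ys))
  for (r in seq_len(nrow(result))) {
    z[match(result[[x_par]][r], xs), match(result[[y_par]][r], ys)] <-
      result[[response]][r]
  }
  graphics::filled.contour(xs, ys, z, xlab = x_par, ylab = y_par,
                           color.palette = grDevices::hcl.colors, ...)
  invisible(NULL)
}
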