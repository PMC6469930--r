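#' Plot a firing-rate map
#'
#' Image of the clipped rate map (97th-percentile clip by default) with the
#' maximum firing rate per bin in the title, excluded bins left blank.
#'
#' @param x a [build_rate_map()] result.
#' @param occ the matching occupancy grid (for bin edges).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.rate_map <- function(x, occ = NULL, ...) {
  z <- x$rate_clipped
  if (!is.null(occ))
    graphics::image(occ$x_centers, occ$y_centers, z, asp = 1,
                    xlab = "x (cm)", ylab = "y (cm)",
                    main = sprintf("%s: max FR/bin %.2f Hz", x$unit_id,
                                   x$max_rate), ...)
  else
    graphics::image(z, main = sprintf("%s: max FR/bin %.2f Hz", x$unit_id,
                                      x$max_rate), ...)
  invisible(x)
}

#' Plot a spike-triggered average
#'
#' Mean trace with a +/- 1 SEM band against lag; lag 0 marks the spike.
#'
#' @param x a `triggered_average`.
#' @param ylab y label (units of the covariate).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.triggered_average <- function(x, ylab = "covariate", ...) {
  graphics::plot(x$lags, x$mean, type = "l", xlab = "lag (s)", ylab = ylab,
                 ...)
  graphics::polygon(c(x$lags, rev(x$lags)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$lags, x$mean)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Plot an egocentric landmark-presence probability map
#'
#' Fish at the center, heading up; excluded (rarely sampled) elements blank.
#'
#' @param x an [accumulate_stlm_ptlm()] result.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.egocentric_map <- function(x, ...) {
  graphics::image(x$dx, x$dy, x$probability, asp = 1,
                  xlab = "left-right (cm)", ylab = "posterior-anterior (cm)",
                  main = sprintf("%s: landmark presence | spike", x$unit_id),
                  ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
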