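#' Instantaneous EOD rate from pulse times
#'
#' The instantaneous rate at time t is the reciprocal of the inter-pulse
#' interval containing t (a step function), sampled on a uniform grid. Before
#' the first pulse and after the last one the rate is extrapolated as a
#' constant (first / last interval value). An optional Gaussian smoother is
#' provided for display; it is off by default and all analyses use the raw
#' step function.
#'
#' @param pulses an [eod_pulse_train()].
#' @param grid_dt grid step (s); default 1/15 s to share the video time base.
#' @param times optional explicit grid (overrides `grid_dt`), e.g.
#'   `trajectory$times` to align with tracking.
#' @param smooth_sd Gaussian smoothing SD (s); 0 disables (default).
#' @return `eod_rate_series`: list with `times` (s), `rate` (Hz), `dt`.
#' @examples
#' p <- eod_pulse_train(seq(0.02, 9.98, by = 0.02), 10)
#' r <- instantaneous_eod_rate(p, grid_dt = 0.1)
#' range(r$rate)  # 50 50
#' @export
instantaneous_eod_rate <- function(pulses, grid_dt = 1 / 15, times = NULL,
                                   smooth_sd = 0) {
  stopifnot(inherits(pulses, "eod_pulse_train"))
  pt <- pulses$pulse_times
  if (length(pt) < 2) stop("need at least 2 pulses to define a rate")
  if (is.null(times)) times <- seq(0, pulses$trial_duration, by = grid_dt)
  dt <- .grid_dt(times)
  isi_rate <- 1 / diff(pt)                       # rate of interval i = [pt_i, pt_{i+1})
  idx <- findInterval(times, pt)                 # 0 before first pulse, n after last
  idx <- pmin(pmax(idx, 1L), length(isi_rate))   # constant extrapolation
  rate <- isi_rate[idx]
  if (smooth_sd > 0) {
    half <- max(1L, ceiling(3 * smooth_sd / dt))
    k <- stats::dnorm(seq(-half, half) * dt, sd = smooth_sd)
    k <- k / sum(k)
    n <- length(rate)
    padded <- c(rep(rate[1], half), rate, rep(rate[n], half))
    rate <- as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
  }
  structure(list(times = as.numeric(times), rate = rate, dt = dt),
            class = "eod_rate_series")
}

#' @export
print.eod_rate_series <- function(x, ...) {
  cat(sprintf("eod_rate_series: %d samples @ %.3g Hz grid, mean %.1f Hz\n",
              length(x$times), 1 / x$dt, mean(x$rate)))
  invisible(x)
}

#' Blank EOD artifacts in an extracellular trace
#'
#' Sets the trace to exactly zero in a window of `half_window` seconds on each
#' side of every EOD pulse (default 2.8 ms, so a 5.6 ms total window).
#' Overlapping windows are blanked as their union; samples outside all windows
#' are untouched. The operation is idempotent.
#'
#' @param trace a [sampled_trace()].
#' @param pulses an [eod_pulse_train()].
#' @param half_window half-width of the blanking window (s).
#' @return The blanked `sampled_trace`.
#' @export
blank_eod_artifacts <- function(trace, pulses, half_window = 2.8e-3) {
  stopifnot(inherits(trace, "sampled_trace"), inherits(pulses, "eod_pulse_train"))
  .stopifnot_scalar_pos(half_window, "half_window")
  n <- length(trace$samples)
  if (!length(pulses$pulse_times) || n == 0L) return(trace)
  sr <- trace$sample_rate
  # a hair of tolerance so samples exactly on the window edge are included
  hw <- half_window * (1 + 1e-9) + 1e-12
  lo <- pmax(1L, as.integer(ceiling((pulses$pulse_times - hw - trace$t0) * sr)) + 1L)
  hi <- pmin(n, as.integer(floor((pulses$pulse_times + hw - trace$t0) * sr)) + 1L)
  keep <- lo <= hi
  zero <- rep(FALSE, n)
  for (k in which(keep)) zero[lo[k]:hi[k]] <- TRUE
  trace$samples[zero] <- 0
  trace
}

#' Count upward threshold crossings
#'
#' A crossing is counted at sample i when `x[i-1] < threshold <= x[i]`. Used
#' to estimate the fraction of neural spikes lost to EOD blanking as
#' `(raw - blanked) / raw`.
#'
#' @param trace a [sampled_trace()].
#' @param threshold detection threshold (same units as the trace).
#' @return integer count of crossings.
#' @export
count_threshold_crossings <- function(trace, threshold) {
  stopifnot(inherits(trace, "sampled_trace"), is.finite(threshold))
  x <- trace$samples
  if (length(x) < 2) return(0L)
  sum(x[-1] >= threshold & x[-length(x)] < threshold)
}

#' Detect EOD pulses from a tank-electrode voltage trace
#'
#' Simple upward threshold crossing detector with a refractory period; pulse
#' times may equally be supplied directly to the rest of the pipeline.
#'
#' @param trace a [sampled_trace()] of tank-electrode voltage.
#' @param threshold detection threshold.
#' @param refractory minimum inter-pulse interval (s), default 5 ms.
#' @return An [eod_pulse_train()].
#' @export
detect_eod_pulses <- function(trace, threshold, refractory = 5e-3) {
  stopifnot(inherits(trace, "sampled_trace"))
  x <- trace$samples
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  t <- trace$t0 + (up - 1L) / trace$sample_rate
  if (length(t) > 1) {
    keep <- c(TRUE, rep(FALSE, length(t) - 1))
    last <- t[1]
    for (k in seq_along(t)[-1]) {
      if (t[k] - last >= refractory) { keep[k] <- TRUE; last <- t[k] }
    }
    t <- t[keep]
  }
  dur <- trace$t0 + length(x) / trace$sample_rate
  eod_pulse_train(t, dur)
}

#' Linear EOD-rate vs speed relationship
#'
#' Ordinary least-squares R-squared of instantaneous EOD rate against swim
#' speed on their shared grid; a descriptive utility for asking how much of
#' the EOD-rate variance speed explains.
#'
#' @param eod_rate an `eod_rate_series`.
#' @param speed a `covariate_series` of speed on the same grid.
#' @return list with `r_squared`, `slope`, `intercept`.
#' @export
eodr_speed_r2 <- function(eod_rate, speed) {
  a <- .series_values(eod_rate); b <- .series_values(speed)
  n <- min(length(a$values), length(b$values))
  fit <- stats::lm(a$values[seq_len(n)] ~ b$values[seq_len(n)])
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
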