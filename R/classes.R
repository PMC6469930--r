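#' Tracked head trajectory
#'
#' Time-stamped 2-D head position and heading of the fish at the video frame
#' rate. Heading is the body-axis direction of the head in radians, measured
#' counter-clockwise from the +x axis and wrapped to (-pi, pi]. Because
#' pulse-type electric fish frequently swim backward, heading is NOT the
#' direction of motion.
#'
#' @param times frame times (s), uniform grid.
#' @param x,y head position (cm).
#' @param heading body-axis direction (radians); `NA` allowed for lost frames.
#' @return `tracked_trajectory` object (a data-frame-like list).
#' @export
tracked_trajectory <- function(times, x, y, heading) {
  n <- length(times)
  stopifnot(length(x) == n, length(y) == n, length(heading) == n, n >= 2)
  dt <- .grid_dt(times)
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y), heading = .wrap_angle(as.numeric(heading)),
                 dt = dt),
            class = "tracked_trajectory")
}

#' @export
print.tracked_trajectory <- function(x, ...) {
  cat(sprintf("tracked_trajectory: %d frames @ %.3g Hz, %.1f s\n",
              length(x$times), 1 / x$dt, x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' EOD pulse train
#'
#' Times of electric organ discharges in one trial. Each pulse is one
#' electrosensory sampling event.
#'
#' @param pulse_times pulse times (s), strictly increasing, in
#'   `[0, trial_duration)`.
#' @param trial_duration trial length (s).
#' @return `eod_pulse_train` object.
#' @export
eod_pulse_train <- function(pulse_times, trial_duration) {
  pulse_times <- as.numeric(pulse_times)
  .stopifnot_scalar_pos(trial_duration, "trial_duration")
  if (length(pulse_times) && any(diff(pulse_times) <= 0))
    stop("pulse times must be strictly increasing")
  if (length(pulse_times) &&
      (pulse_times[1] < 0 || pulse_times[length(pulse_times)] >= trial_duration))
    stop("pulse times must lie in [0, trial_duration)")
  structure(list(pulse_times = pulse_times, trial_duration = trial_duration),
            class = "eod_pulse_train")
}

#' @export
print.eod_pulse_train <- function(x, ...) {
  cat(sprintf("eod_pulse_train: %d pulses over %.1f s (mean %.1f Hz)\n",
              length(x$pulse_times), x$trial_duration,
              length(x$pulse_times) / x$trial_duration))
  invisible(x)
}

#' Sorted spike train for one unit
#'
#' @param spike_times spike times (s), strictly increasing, within the trial.
#' @param trial_duration trial length (s).
#' @param unit_id,trial_id identifiers.
#' @return `spike_train` object.
#' @export
spike_train <- function(spike_times, trial_duration, unit_id = "u1",
                        trial_id = "t1") {
  spike_times <- as.numeric(spike_times)
  .stopifnot_scalar_pos(trial_duration, "trial_duration")
  if (length(spike_times) && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing")
  if (length(spike_times) &&
      (spike_times[1] < 0 || spike_times[length(spike_times)] > trial_duration))
    stop("spike times must lie within the trial")
  structure(list(spike_times = spike_times, trial_duration = trial_duration,
                 unit_id = unit_id, trial_id = trial_id),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train %s/%s: %d spikes over %.1f s (%.3g Hz)\n",
              x$trial_id, x$unit_id, length(x$spike_times), x$trial_duration,
              length(x$spike_times) / x$trial_duration))
  invisible(x)
}

#' Uniformly sampled voltage trace
#'
#' @param samples numeric vector of voltage samples (arbitrary units).
#' @param sample_rate sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @return `sampled_trace` object.
#' @export
sampled_trace <- function(samples, sample_rate, t0 = 0) {
  .stopifnot_scalar_pos(sample_rate, "sample_rate")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 t0 = t0),
            class = "sampled_trace")
}

#' Covariate series on a uniform grid
#'
#' Generic container for a behavioral covariate (swim speed, sampling
#' density, ...) sampled on the trajectory time base; the EOD rate has its own
#' class [instantaneous_eod_rate()].
#'
#' @param times times (s), uniform grid.
#' @param values covariate values.
#' @param units unit string (for printing).
#' @return `covariate_series` object.
#' @export
covariate_series <- function(times, values, units = "") {
  stopifnot(length(times) == length(values))
  dt <- .grid_dt(times)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 dt = dt, units = units),
            class = "covariate_series")
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("covariate_series [%s]: %d samples @ %.3g Hz\n",
              x$units, length(x$times), 1 / x$dt))
  invisible(x)
}

# extract a uniform (times, values) pair from any supported series type
.series_values <- function(series) {
  if (inherits(series, "eod_rate_series"))
    list(times = series$times, values = series$rate, dt = series$dt)
  else if (inherits(series, "covariate_series"))
    list(times = series$times, values = series$values, dt = series$dt)
  else if (is.list(series) && !is.null(series$times)) {
    v <- if (!is.null(series$values)) series$values else series$rate
    list(times = series$times, values = v, dt = .grid_dt(series$times))
  } else stop("unsupported series type")
}
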