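#' Swim speed from the tracked trajectory
#'
#' Speed is the magnitude of the central-difference velocity
#' `(p[i+1] - p[i-1]) / (2 dt)` (one-sided at the trial edges), optionally
#' boxcar-smoothed over an odd number of frames.
#'
#' @param traj a [tracked_trajectory()].
#' @param smooth_window boxcar width in frames (odd; 1 = no smoothing).
#' @return `covariate_series` of speed (cm/s) with one value per frame.
#' @export
compute_speed <- function(traj, smooth_window = 1L) {
  stopifnot(inherits(traj, "tracked_trajectory"))
  v <- .velocity(traj)
  sp <- sqrt(v$vx^2 + v$vy^2)
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
    k <- rep(1 / smooth_window, smooth_window)
    half <- (smooth_window - 1L) %/% 2L
    n <- length(sp)
    padded <- c(rep(sp[1], half), sp, rep(sp[n], half))
    sp <- as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
  }
  covariate_series(traj$times, sp, units = "cm/s")
}

# central-difference velocity, one-sided at the ends
.velocity <- function(traj) {
  n <- length(traj$times)
  dt <- traj$dt
  vx <- numeric(n); vy <- numeric(n)
  vx[2:(n - 1)] <- (traj$x[3:n] - traj$x[1:(n - 2)]) / (2 * dt)
  vy[2:(n - 1)] <- (traj$y[3:n] - traj$y[1:(n - 2)]) / (2 * dt)
  vx[1] <- (traj$x[2] - traj$x[1]) / dt; vy[1] <- (traj$y[2] - traj$y[1]) / dt
  vx[n] <- (traj$x[n] - traj$x[n - 1]) / dt; vy[n] <- (traj$y[n] - traj$y[n - 1]) / dt
  list(vx = vx, vy = vy)
}

#' Classify frames as forward, backward or quiescent swimming
#'
#' Pulse-type electric fish swim backward routinely; the tracked heading
#' follows the body axis (head direction), not the direction of motion. A
#' frame is *backward* when the velocity projects negatively on the body axis
#' and the speed is at least `speed_threshold`; *forward* when the projection
#' is non-negative at or above threshold; *quiescent* otherwise. Turns are
#' pooled with the swim state of matching projection sign, so no separate
#' turn detector is needed. Frames with missing heading become quiescent.
#'
#' @param traj a [tracked_trajectory()].
#' @param speed_threshold minimum speed (cm/s) to count as swimming
#'   (default 1).
#' @param smooth_window boxcar width (frames) for the speed used in the
#'   threshold; see [compute_speed()].
#' @return `swim_labels` object: `labels` (factor forward/backward/quiescent
#'   per frame), `speed` (cm/s), `times`, `dt`.
#' @export
classify_swim_direction <- function(traj, speed_threshold = 1,
                                    smooth_window = 1L) {
  stopifnot(inherits(traj, "tracked_trajectory"))
  v <- .velocity(traj)
  sp <- compute_speed(traj, smooth_window = smooth_window)$values
  proj <- v$vx * cos(traj$heading) + v$vy * sin(traj$heading)
  lab <- rep("quiescent", length(sp))
  moving <- sp >= speed_threshold & !is.na(traj$heading)
  lab[moving & proj >= 0] <- "forward"
  lab[moving & proj < 0] <- "backward"
  n_missing <- sum(is.na(traj$heading))
  if (n_missing > 0)
    message(sprintf("%d frame(s) with missing heading labeled quiescent", n_missing))
  structure(list(labels = factor(lab, levels = c("forward", "backward", "quiescent")),
                 speed = sp, times = traj$times, dt = traj$dt),
            class = "swim_labels")
}

#' @export
print.swim_labels <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("swim_labels: %d frames (%.1f%% fwd, %.1f%% bwd, %.1f%% quiescent)\n",
              length(x$labels), 100 * tab[1] / length(x$labels),
              100 * tab[2] / length(x$labels), 100 * tab[3] / length(x$labels)))
  invisible(x)
}

#' Detect EOD-rate down states
#'
#' Maximal intervals where the instantaneous EOD rate stays below `threshold`
#' (default 50 Hz, the conventional down-state bound for *Gymnotus*), keeping
#' only intervals of at least `min_duration` seconds.
#'
#' @param eod_rate an `eod_rate_series`.
#' @param threshold rate threshold (Hz).
#' @param min_duration minimum interval length (s), default 1.
#' @return data.frame with columns `start`, `end` (s); zero rows if none.
#' @export
detect_down_states <- function(eod_rate, threshold = 50, min_duration = 1) {
  stopifnot(inherits(eod_rate, "eod_rate_series"))
  below <- eod_rate$rate < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = numeric(0), end = numeric(0)))
  dt <- eod_rate$dt
  out <- data.frame(start = eod_rate$times[starts[keep]],
                    end = eod_rate$times[ends[keep]] + dt)
  out[out$end - out$start >= min_duration, , drop = FALSE]
}
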