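#' Movement-model parameters for the trajectory generator
#'
#' The generator is a correlated random walk on heading with smooth wall
#' avoidance, a landmark-attraction steering term and slowed swimming close
#' to landmarks (producing the wall/landmark occupancy bias the spatial
#' analyses assume), interleaved with backward-swim episodes (velocity
#' antiparallel to the body axis — heading tracks the body, not the motion)
#' and quiescent episodes (down states). Defaults emulate a *Gymnotus*-like
#' session; backward-scan kinematics are free parameters of the model, not
#' measurements.
#'
#' @param speed_mean,speed_sd mean and SD of active swim speed (cm/s).
#' @param speed_tau relaxation time of the speed process (s).
#' @param turn_sd heading diffusion (rad per sqrt(s)).
#' @param max_turn maximum heading change per frame (rad).
#' @param backward_rate rate of backward-episode onsets (1/s).
#' @param backward_duration mean backward-episode duration (s, exponential).
#' @param quiescent_rate rate of quiescent-episode onsets (1/s).
#' @param quiescent_duration mean quiescent-episode duration (s).
#' @param approach_rate rate of landmark-approach bouts (1/s); during a bout
#'   the fish steers toward a randomly chosen landmark.
#' @param approach_duration mean bout duration (s).
#' @param approach_gain steering gain during a bout (fraction of the angular
#'   error corrected per frame).
#' @param dwell_slow speed multiplier within `dwell_dist` of a landmark.
#' @param dwell_dist distance for slowed swimming (cm).
#' @param wall_margin distance from the wall where avoidance starts (cm).
#' @param wall_gain steering gain of wall avoidance.
#' @return named list of parameters.
#' @export
trajectory_params <- function(speed_mean = 8, speed_sd = 4, speed_tau = 2,
                              turn_sd = 1.2, max_turn = 0.5,
                              backward_rate = 0.05, backward_duration = 2,
                              quiescent_rate = 1 / 180,
                              quiescent_duration = 15,
                              approach_rate = 0.08,
                              approach_duration = 5,
                              approach_gain = 0.15,
                              dwell_slow = 0.4, dwell_dist = 5,
                              wall_margin = 8, wall_gain = 0.35) {
  as.list(environment())
}

#' Generate a synthetic tracked trajectory
#'
#' See [trajectory_params()] for the movement model. Positions are guaranteed
#' to stay inside the tank and outside solid landmark polygons; heading is
#' continuous (per-frame change capped at `max_turn`). Ground-truth
#' forward/backward/quiescent labels are returned alongside the trajectory.
#'
#' @param arena an [arena_layout()].
#' @param duration trial duration (s).
#' @param frame_rate video frame rate (Hz), default 15.
#' @param params a [trajectory_params()] list.
#' @param seed RNG seed.
#' @return `synthetic_trajectory`: `trajectory` (a [tracked_trajectory()]),
#'   `labels` (ground-truth factor per frame), `arena`, `params`, `seed`.
#' @export
generate_trajectory <- function(arena = default_arena(), duration = 1800,
                                frame_rate = 15,
                                params = trajectory_params(), seed = 1) {
  stopifnot(inherits(arena, "arena_layout"))
  .stopifnot_scalar_pos(duration, "duration")
  .stopifnot_scalar_pos(frame_rate, "frame_rate")
  dt <- 1 / frame_rate
  if ((params$speed_mean + 6 * params$speed_sd) * dt >= 2 * arena$tank_radius)
    stop("movement parameters imply speeds that cross the tank in one frame")
  n <- as.integer(round(duration * frame_rate))
  ctr <- arena$tank_center; R <- arena$tank_radius
  cents <- lapply(c(arena$landmarks,
                    if (!is.null(arena$home)) list(arena$home)),
                  colMeans)
  with_seed(seed, {
    x <- numeric(n); y <- numeric(n); h <- numeric(n)
    lab <- character(n)
    x[1] <- ctr[1]; y[1] <- ctr[2] + R / 2
    h[1] <- stats::runif(1, -pi, pi)
    sp <- params$speed_mean
    state <- "forward"; state_left <- Inf
    approach_left <- 0; approach_target <- NULL
    alpha <- dt / params$speed_tau
    for (i in seq_len(n)) {
      if (i > 1) {
        # episode bookkeeping
        if (state != "forward") {
          state_left <- state_left - dt
          if (state_left <= 0) state <- "forward"
        }
        if (state == "forward") {
          u <- stats::runif(2)
          if (u[1] < params$backward_rate * dt) {
            state <- "backward"
            state_left <- stats::rexp(1, 1 / params$backward_duration)
          } else if (u[2] < params$quiescent_rate * dt) {
            state <- "quiescent"
            state_left <- stats::rexp(1, 1 / params$quiescent_duration)
          }
        }
        # speed: AR(1) toward the mean
        sp <- sp + alpha * (params$speed_mean - sp) +
          params$speed_sd * sqrt(2 * alpha) * stats::rnorm(1)
        sp <- max(sp, 0.5)
        speed_now <- if (state == "quiescent") abs(stats::rnorm(1, 0, 0.1)) else sp
        dlm <- landmark_distance(arena, x[i - 1], y[i - 1])
        if (is.finite(dlm) && dlm <= params$dwell_dist && state != "quiescent")
          speed_now <- speed_now * params$dwell_slow
        # active swimming stays above the quiescence threshold so the
        # ground-truth labels remain well defined
        if (state != "quiescent") speed_now <- max(speed_now, 1.5)
        # heading: diffusion + intermittent landmark-approach bouts + wall
        # avoidance
        dh <- params$turn_sd * sqrt(dt) * stats::rnorm(1)
        if (length(cents)) {
          if (approach_left <= 0 && state == "forward" &&
              stats::runif(1) < params$approach_rate * dt) {
            approach_target <- cents[[sample.int(length(cents), 1)]]
            approach_left <- stats::rexp(1, 1 / params$approach_duration)
          }
          if (approach_left > 0) {
            approach_left <- approach_left - dt
            if (is.finite(dlm) && dlm <= params$dwell_dist)
              approach_left <- 0     # arrived: dwell, then resume roaming
            else if (state == "forward") {
              want <- atan2(approach_target[2] - y[i - 1],
                            approach_target[1] - x[i - 1])
              dh <- dh + params$approach_gain * .wrap_angle(want - h[i - 1])
            }
          }
        }
        motion_dir <- if (state == "backward") h[i - 1] + pi else h[i - 1]
        rad <- sqrt((x[i - 1] - ctr[1])^2 + (y[i - 1] - ctr[2])^2)
        if (rad > R - params$wall_margin) {
          inward <- atan2(ctr[2] - y[i - 1], ctr[1] - x[i - 1])
          corr <- params$wall_gain * .wrap_angle(inward - motion_dir)
          dh <- dh + if (state == "backward") -corr else corr
        }
        dh <- max(-params$max_turn, min(params$max_turn, dh))
        h[i] <- .wrap_angle(h[i - 1] + dh)
        dir <- if (state == "backward") h[i] + pi else h[i]
        nx_ <- x[i - 1] + speed_now * dt * cos(dir)
        ny_ <- y[i - 1] + speed_now * dt * sin(dir)
        # keep inside the tank (radial clamp) and out of solid landmarks
        rr <- sqrt((nx_ - ctr[1])^2 + (ny_ - ctr[2])^2)
        if (rr > R - 1) {
          nx_ <- ctr[1] + (nx_ - ctr[1]) * (R - 1) / rr
          ny_ <- ctr[2] + (ny_ - ctr[2]) * (R - 1) / rr
        }
        if (.in_solid_landmark(arena, nx_, ny_)) {
          nx_ <- x[i - 1]; ny_ <- y[i - 1]
        }
        x[i] <- nx_; y[i] <- ny_
      }
      lab[i] <- if (i == 1) "forward" else state
    }
    traj <- tracked_trajectory(times = (seq_len(n) - 1) * dt, x = x, y = y,
                               heading = h)
    structure(list(trajectory = traj,
                   labels = factor(lab, levels = c("forward", "backward",
                                                   "quiescent")),
                   arena = arena, params = params, seed = seed),
              class = "synthetic_trajectory")
  })
}

#' @export
print.synthetic_trajectory <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("synthetic_trajectory (seed %s): %d frames; fwd/bwd/quiet = %d/%d/%d\n",
              format(x$seed), length(x$labels), tab[1], tab[2], tab[3]))
  invisible(x)
}

#' EOD-train parameters
#'
#' @param base_rate active-state EOD rate (Hz), default 70.
#' @param down_rate down-state EOD rate (Hz), must stay below the 50 Hz
#'   down-state convention; default 40.
#' @param transient_amp EOD-rate increase near landmarks (Hz), default 30.
#' @param transient_dist distance triggering the transient (cm), default 3.
#' @param transient_tau transient rise/decay time constant (s), default 0.5.
#' @param shape gamma ISI shape (1 = Poisson; larger = quasi-regular).
#'   Real EOD trains are clock-like, with ISI jitter of a few percent; the
#'   default of 500 gives an ISI coefficient of variation of about 4.5%.
#' @return named list.
#' @export
eod_params <- function(base_rate = 70, down_rate = 40, transient_amp = 30,
                       transient_dist = 3, transient_tau = 0.5, shape = 500) {
  p <- as.list(environment())
  if (p$base_rate <= 0 || p$down_rate <= 0 || p$shape <= 0)
    stop("rates and shape must be positive")
  if (p$transient_amp < 0) stop("transient_amp must be >= 0")
  p
}

#' Generate a synthetic EOD pulse train
#'
#' An inhomogeneous renewal process with gamma-distributed rescaled
#' inter-pulse intervals (shape 1 recovers a Poisson process): real EOD
#' trains are quasi-regular. The target rate follows the behavioral state —
#' `base_rate` while active, `down_rate` (< 50 Hz) during ground-truth
#' quiescence — plus a smoothed transient of `transient_amp` Hz whenever the
#' fish is within `transient_dist` of a landmark, mimicking sampling-rate
#' increases near objects.
#'
#' @param straj a [generate_trajectory()] result.
#' @param params an [eod_params()] list.
#' @param seed RNG seed.
#' @return An [eod_pulse_train()] with attribute `target_rate` (the per-frame
#'   rate used, Hz).
#' @export
generate_eod_train <- function(straj, params = eod_params(), seed = 1) {
  stopifnot(inherits(straj, "synthetic_trajectory"))
  traj <- straj$trajectory
  dt <- traj$dt
  n <- length(traj$times)
  quiet <- straj$labels == "quiescent"
  base <- ifelse(quiet, params$down_rate, params$base_rate)
  trans <- numeric(n)
  if (params$transient_amp > 0 && length(straj$arena$landmarks) +
      !is.null(straj$arena$home) > 0) {
    near <- landmark_distance(straj$arena, traj$x, traj$y) <= params$transient_dist
    target <- ifelse(near, params$transient_amp, 0)
    a <- 1 - exp(-dt / params$transient_tau)
    for (i in 2:n) trans[i] <- trans[i - 1] + a * (target[i] - trans[i - 1])
    trans[quiet] <- 0
  }
  rate <- base + trans
  cumL <- c(0, cumsum(rate * dt))
  total <- cumL[n + 1]
  k <- params$shape
  with_seed(seed, {
    n_draw <- as.integer(ceiling(total + 6 * sqrt(total / k) + 20))
    g <- cumsum(stats::rgamma(n_draw, shape = k, rate = k))
    g <- g[g < total]
    t <- stats::approx(x = cumL, y = c(traj$times, traj$times[n] + dt),
                       xout = g, ties = "ordered")$y
    out <- eod_pulse_train(t, traj$times[n] + dt)
    attr(out, "target_rate") <- rate
    out
  })
}

#' Ground-truth effect structure for the spike generator
#'
#' Encodes the effects the analyses are designed to detect, so each can be
#' switched on to test parameter recovery or off to calibrate false-positive
#' rates. Spike intensity is
#' `baseline x place-field gain x direction gain x EOD-coupling gain x
#' speed-coupling gain x landmark-driver gain`, forced toward zero during
#' ground-truth quiescence unless `quiescent_suppression` is disabled.
#'
#' @param baseline_rate baseline spike rate (Hz), default 0.5 (DDi-like
#'   sparseness).
#' @param place_fields list of fields, each `list(center = c(x, y), radius,
#'   gain)`; the gain is the multiplicative peak factor of a Gaussian bump
#'   with SD `radius / 2`.
#' @param direction_gain intensity multiplier during backward swim
#'   (dimensionless, >= 0; `Inf` makes forward intensity zero).
#' @param eod_coupling `NULL` or `list(lag, gain)`: intensity is multiplied
#'   by `exp(gain * z(t + lag))` where `z` is the standardized EOD rate —
#'   `lag < 0` makes the EOD-rate elevation precede spikes.
#' @param speed_coupling `NULL` or `list(lag, gain)`, same convention on
#'   standardized speed — `lag > 0` makes the speed elevation follow spikes.
#' @param landmark_driver `NULL` or `list(offset = c(right, anterior),
#'   radius, gain)`: intensity multiplied by `gain` whenever a landmark lies
#'   within `radius` cm of the probe point at the given egocentric offset
#'   (cm) from the head.
#' @param quiescent_suppression multiply intensity by 0.02 during
#'   ground-truth quiescence (default TRUE).
#' @return `ground_truth` list.
#' @export
ground_truth <- function(baseline_rate = 0.5, place_fields = list(),
                         direction_gain = 1, eod_coupling = NULL,
                         speed_coupling = NULL, landmark_driver = NULL,
                         quiescent_suppression = TRUE) {
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (direction_gain < 0) stop("direction_gain must be >= 0")
  for (f in place_fields)
    if (f$gain < 0 || f$radius <= 0) stop("place-field gain/radius invalid")
  structure(as.list(environment()), class = "ground_truth")
}

#' Generate a synthetic spike train
#'
#' Inhomogeneous point process driven by the [ground_truth()] intensity
#' model, discretized per video frame (counts Poisson within a frame, times
#' jittered uniformly inside it). With default parameters the mean rate
#' stays below ~1 Hz, matching the sparseness of DDi units.
#'
#' @param straj a [generate_trajectory()] result.
#' @param eod_rate an `eod_rate_series` on the trajectory grid (needed when
#'   `truth$eod_coupling` is set; may be `NULL` otherwise).
#' @param truth a [ground_truth()].
#' @param seed RNG seed.
#' @param unit_id unit identifier.
#' @return A [spike_train()] with attribute `truth`.
#' @export
generate_spikes <- function(straj, eod_rate = NULL, truth = ground_truth(),
                            seed = 1, unit_id = "u1") {
  stopifnot(inherits(straj, "synthetic_trajectory"),
            inherits(truth, "ground_truth"))
  traj <- straj$trajectory
  dt <- traj$dt
  n <- length(traj$times)
  lam <- rep(truth$baseline_rate, n)
  for (f in truth$place_fields) {
    d2 <- (traj$x - f$center[1])^2 + (traj$y - f$center[2])^2
    s2 <- (f$radius / 2)^2
    lam <- lam * (1 + (f$gain - 1) * exp(-d2 / (2 * s2)))
  }
  bwd <- straj$labels == "backward"
  if (is.infinite(truth$direction_gain)) {
    lam[straj$labels == "forward"] <- 0
  } else if (truth$direction_gain != 1) {
    lam[bwd] <- lam[bwd] * truth$direction_gain
  }
  z_shift <- function(v, lag) {
    z <- as.numeric(scale(v))
    k <- as.integer(round(lag / dt))
    out <- rep(0, n)
    src <- seq_len(n) + k
    ok <- src >= 1 & src <= n
    out[ok] <- z[src[ok]]
    out
  }
  if (!is.null(truth$eod_coupling)) {
    if (is.null(eod_rate)) stop("eod_rate needed for EOD coupling")
    r <- .series_values(eod_rate)$values
    if (length(r) != n) stop("eod_rate must be on the trajectory grid")
    lam <- lam * exp(truth$eod_coupling$gain *
                       z_shift(r, truth$eod_coupling$lag))
  }
  if (!is.null(truth$speed_coupling)) {
    sp <- compute_speed(traj)$values
    lam <- lam * exp(truth$speed_coupling$gain *
                       z_shift(sp, truth$speed_coupling$lag))
  }
  if (!is.null(truth$landmark_driver)) {
    ld <- truth$landmark_driver
    a_x <- cos(traj$heading); a_y <- sin(traj$heading)
    px <- traj$x + ld$offset[1] * a_y + ld$offset[2] * a_x
    py <- traj$y - ld$offset[1] * a_x + ld$offset[2] * a_y
    near <- landmark_distance(straj$arena, px, py) <= ld$radius
    lam[near] <- lam[near] * ld$gain
  }
  if (truth$quiescent_suppression)
    lam[straj$labels == "quiescent"] <- lam[straj$labels == "quiescent"] * 0.02
  with_seed(seed, {
    counts <- stats::rpois(n, lam * dt)
    t <- rep(traj$times, counts) + stats::runif(sum(counts)) * dt
    t <- sort(t)
    t <- t[c(TRUE, diff(t) > 0)]       # strictly increasing
    out <- spike_train(t, traj$times[n] + dt, unit_id = unit_id)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a complete synthetic trial
#'
#' Arena + trajectory + EOD train + spike trains with known ground truth, so
#' every analysis stage can be tested by parameter recovery. All randomness
#' derives from `seed`; identical seed and parameters give bit-identical
#' output.
#'
#' @param arena an [arena_layout()].
#' @param duration trial duration (s), default 1800 (a 30 min trial).
#' @param frame_rate video rate (Hz), default 15.
#' @param traj_params [trajectory_params()].
#' @param eod_params [eod_params()].
#' @param truth a [ground_truth()] or a list of them (one spike train each).
#' @param seed master seed.
#' @return `trial_bundle`: `arena`, `straj` (synthetic trajectory with
#'   ground-truth labels), `trajectory`, `eod`, `eod_rate` (on the video
#'   grid), `units` (list of [spike_train()]), `ground_truth`, `seed`.
#' @export
simulate_trial <- function(arena = default_arena(), duration = 1800,
                           frame_rate = 15,
                           traj_params = trajectory_params(),
                           eod_params = eodmaps::eod_params(),
                           truth = ground_truth(), seed = 1) {
  truths <- if (inherits(truth, "ground_truth")) list(truth) else truth
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    2L + length(truths)))
  straj <- generate_trajectory(arena, duration, frame_rate, traj_params,
                               seed = sub[1])
  eod <- generate_eod_train(straj, eod_params, seed = sub[2])
  eod_rate <- instantaneous_eod_rate(eod, times = straj$trajectory$times)
  units <- lapply(seq_along(truths), function(k)
    generate_spikes(straj, eod_rate, truths[[k]], seed = sub[2 + k],
                    unit_id = sprintf("u%02d", k)))
  structure(list(arena = arena, straj = straj,
                 trajectory = straj$trajectory, eod = eod,
                 eod_rate = eod_rate, units = units,
                 ground_truth = truths, seed = seed,
                 frame_rate = frame_rate, duration = duration),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf("trial_bundle (seed %s): %.0f s @ %g Hz, %d pulses, %d unit(s)\n",
              format(x$seed), x$duration, x$frame_rate,
              length(x$eod$pulse_times), length(x$units)))
  invisible(x)
}
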