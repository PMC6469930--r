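#' Analysis configuration
#'
#' Collects every threshold of the pipeline with its conventional default:
#' 16 cm spatial bins with a 5-visit inclusion rule, 97th-percentile display
#' clipping, +/- 4 s spike-triggered windows with 100 circular shifts (1000
#' for place information) of at least 30 s, 2.8 ms EOD blanking half-window,
#' 50 Hz down-state threshold, 10 cm landmark-effect radius, 1.33 s PTLM
#' downsampling, 0.5 cm/s speed floor for sampling density, 1 cm/s
#' quiescence speed threshold and 15 cm body length. All values are
#' overridable and the configuration is echoed into every report.
#'
#' @param ... overrides of the defaults listed above.
#' @return `analysis_config` list.
#' @export
analysis_config <- function(...) {
  cfg <- list(bin_size = 16, visit_min = 5L, display_clip = 97,
              half_window = 4, n_shifts = 100L, n_shifts_place = 1000L,
              min_shift = 30, blank_half_window = 2.8e-3,
              down_threshold = 50, down_min_duration = 1,
              landmark_radius = 10, downsample_dt = 1.33,
              egocentric_window = 10, exclude_pct = 10,
              speed_floor = 0.5, speed_threshold = 1,
              body_length = 15, min_spikes = 10L, alpha = 0.05,
              seed = 1L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

.write_num_csv <- function(df, path) {
  cols <- lapply(df, function(v) sprintf("%.17g", v))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

#' Write a trial bundle to disk
#'
#' Emits the interchange files the readers consume: `trajectory.csv`
#' (`t,x_cm,y_cm,heading_rad`), `eod_pulses.csv` (`t`), one
#' `spikes_<unit>.csv` (`t`) per unit, `arena.json`, and — for synthetic
#' trials — a `ground_truth.json` sidecar including the seed. Numbers are
#' written with full double precision so a round trip is lossless.
#'
#' @param bundle a `trial_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(bundle, dir) {
  stopifnot(inherits(bundle, "trial_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- bundle$trajectory
  .write_num_csv(data.frame(t = tr$times, x_cm = tr$x, y_cm = tr$y,
                            heading_rad = tr$heading),
                 file.path(dir, "trajectory.csv"))
  .write_num_csv(data.frame(t = bundle$eod$pulse_times),
                 file.path(dir, "eod_pulses.csv"))
  for (u in bundle$units)
    .write_num_csv(data.frame(t = u$spike_times),
                   file.path(dir, sprintf("spikes_%s.csv", u$unit_id)))
  a <- bundle$arena
  arena_js <- list(tank_center = a$tank_center, tank_radius = a$tank_radius,
                   pixel_scale = a$pixel_scale, video_size = a$video_size,
                   landmarks = lapply(a$landmarks, function(p)
                     list(x = p[, 1], y = p[, 2])),
                   home = if (is.null(a$home)) NULL else
                     list(x = a$home[, 1], y = a$home[, 2]),
                   duration = bundle$duration, frame_rate = bundle$frame_rate)
  jsonlite::write_json(arena_js, file.path(dir, "arena.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(bundle$ground_truth)) {
    gt <- lapply(bundle$ground_truth, function(g) unclass(g))
    jsonlite::write_json(list(seed = bundle$seed, units = gt,
                              labels = as.character(bundle$straj$labels)),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Load a trial bundle from disk
#'
#' Reads the interchange files written by [write_trial()] (or prepared by
#' hand in the same dialects), validates their schemas, repairs single
#' missing frames by linear interpolation (with a message) and rejects
#' non-monotone spike or pulse times.
#'
#' @param dir directory holding `trajectory.csv`, `eod_pulses.csv`,
#'   `arena.json` and `spikes_*.csv` files.
#' @return A `trial_bundle` (without synthetic ground-truth labels; the
#'   `ground_truth.json` sidecar, if present, is attached as `ground_truth`).
#' @export
load_trial <- function(dir) {
  need <- c("trajectory.csv", "eod_pulses.csv", "arena.json")
  for (f in need)
    if (!file.exists(file.path(dir, f))) stop("missing file: ", f)
  aj <- jsonlite::read_json(file.path(dir, "arena.json"), simplifyVector = TRUE)
  lms <- lapply(aj$landmarks, function(p) cbind(p$x, p$y))
  arena <- arena_layout(tank_center = aj$tank_center,
                        tank_radius = aj$tank_radius,
                        landmarks = lms,
                        home = if (is.null(aj$home)) NULL else
                          cbind(aj$home$x, aj$home$y),
                        pixel_scale = aj$pixel_scale,
                        video_size = aj$video_size)
  td <- utils::read.csv(file.path(dir, "trajectory.csv"))
  req <- c("t", "x_cm", "y_cm", "heading_rad")
  miss <- setdiff(req, names(td))
  if (length(miss)) stop("trajectory.csv lacks column(s): ",
                         paste(miss, collapse = ", "))
  td <- .repair_frame_gaps(td)
  traj <- tracked_trajectory(td$t, td$x_cm, td$y_cm, td$heading_rad)
  pt <- utils::read.csv(file.path(dir, "eod_pulses.csv"))
  if (!"t" %in% names(pt)) stop("eod_pulses.csv lacks column: t")
  duration <- if (!is.null(aj$duration)) aj$duration else
    max(td$t) + stats::median(diff(td$t))
  eod <- eod_pulse_train(pt$t, duration)
  spike_files <- sort(list.files(dir, pattern = "^spikes_.*\\.csv$"))
  units <- lapply(spike_files, function(f) {
    sd_ <- utils::read.csv(file.path(dir, f))
    if (!"t" %in% names(sd_)) stop(f, " lacks column: t")
    if (is.unsorted(sd_$t, strictly = TRUE))
      stop(f, ": spike times are not strictly increasing")
    spike_train(sd_$t, duration,
                unit_id = sub("^spikes_(.*)\\.csv$", "\\1", f))
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gt_path))
    jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  structure(list(arena = arena, straj = NULL, trajectory = traj, eod = eod,
                 eod_rate = instantaneous_eod_rate(eod, times = traj$times),
                 units = units, ground_truth = gt,
                 seed = if (!is.null(gt)) gt$seed else NA,
                 frame_rate = 1 / stats::median(diff(td$t)),
                 duration = duration),
            class = "trial_bundle")
}

# interpolate single-frame gaps in a trajectory table
.repair_frame_gaps <- function(td) {
  dt <- stats::median(diff(td$t))
  gaps <- which(diff(td$t) > 1.5 * dt & diff(td$t) < 2.5 * dt)
  if (length(gaps)) {
    message(sprintf("interpolated %d single-frame gap(s) in trajectory",
                    length(gaps)))
    full_t <- seq(td$t[1], td$t[nrow(td)], by = dt)
    out <- data.frame(t = full_t)
    for (col in c("x_cm", "y_cm", "heading_rad"))
      out[[col]] <- stats::approx(td$t, td[[col]], xout = full_t)$y
    out
  } else td
}

#' Run the full analysis session on one trial
#'
#' Orchestrates every stage in order: EOD rate, swim speed and direction
#' labels, down states, then per eligible unit the spike-triggered
#' EOD-rate/speed/sampling-density averages with their circular-shift null,
#' mean-elevation and peak tests and peak/dip timing; the occupancy and
#' firing-rate maps with Skaggs information and its permutation
#' significance; the stationarity check; the direction preference index; and
#' the egocentric landmark maps with AP/LR preference vectors. Units with
#' fewer than `config$min_spikes` spikes are reported as skipped; per-unit
#' failures are isolated and do not abort the session.
#'
#' @param bundle a `trial_bundle` (from [simulate_trial()] or
#'   [load_trial()]).
#' @param config an [analysis_config()].
#' @return `session_report`: `config`, `seed`, `down_states`, and `units`, a
#'   named list of per-unit result lists.
#' @export
run_session <- function(bundle, config = analysis_config()) {
  stopifnot(inherits(bundle, "trial_bundle"))
  traj <- bundle$trajectory
  eod_rate <- bundle$eod_rate
  speed <- compute_speed(traj)
  labels <- classify_swim_direction(traj, config$speed_threshold)
  downs <- detect_down_states(eod_rate, config$down_threshold,
                              config$down_min_duration)
  occ <- build_occupancy(traj, bundle$arena, config$bin_size, config$visit_min)
  raster <- rasterize_arena(bundle$arena)
  units <- stats::setNames(
    lapply(seq_along(bundle$units), function(k) {
      u <- bundle$units[[k]]
      res <- try(.analyze_unit(u, eod_rate, speed, labels, occ, raster, traj,
                               config, unit_seed = config$seed + k), silent = TRUE)
      if (inherits(res, "try-error"))
        list(unit_id = u$unit_id, skipped = TRUE,
             reason = conditionMessage(attr(res, "condition")))
      else res
    }),
    vapply(bundle$units, function(u) u$unit_id, character(1)))
  structure(list(config = config, seed = config$seed,
                 down_states = downs, units = units,
                 trial_duration = bundle$duration),
            class = "session_report")
}

.analyze_unit <- function(u, eod_rate, speed, labels, occ, raster, traj,
                          config, unit_seed) {
  out <- list(unit_id = u$unit_id, n_spikes = length(u$spike_times),
              skipped = FALSE)
  if (length(u$spike_times) < config$min_spikes) {
    out$skipped <- TRUE
    out$reason <- sprintf("%d spikes < min_spikes", length(u$spike_times))
    return(out)
  }
  st_eod <- spike_triggered_average(eod_rate, u, config$half_window,
                                    config$min_spikes)
  st_sp <- spike_triggered_average(speed, u, config$half_window,
                                   config$min_spikes)
  if (!is.null(st_eod) && !is.null(st_sp)) {
    st_sd <- st_sampling_density(st_eod, st_sp, config$speed_floor)
    null <- circular_shift_null(u, config$n_shifts, config$min_shift,
                                seed = unit_seed)
    null_eod <- null_triggered_averages(eod_rate, null, config$half_window,
                                        config$min_spikes)
    null_sp <- null_triggered_averages(speed, null, config$half_window,
                                       config$min_spikes)
    out$sta <- list(
      st_eodr = st_eod[c("lags", "mean", "sem", "n_spikes")],
      st_speed = st_sp[c("lags", "mean", "sem", "n_spikes")],
      st_smpd = st_sd[c("lags", "mean", "sem", "n_spikes", "n_excluded")],
      mean_elevation_eodr = test_mean_elevation(st_eod, null_eod),
      mean_elevation_speed = test_mean_elevation(st_sp, null_sp),
      peak_eodr = test_peak(st_eod, "peak", config$min_spikes),
      peak_speed = test_peak(st_sp, "peak", config$min_spikes),
      timing = list(
        eodr_peak = unclass(peak_dip_timing(st_eod, "peak"))[c("median", "p_sign", "n_excluded")],
        speed_peak = unclass(peak_dip_timing(st_sp, "peak"))[c("median", "p_sign", "n_excluded")],
        speed_dip = unclass(peak_dip_timing(st_sp, "dip"))[c("median", "p_sign", "n_excluded")],
        smpd_peak = unclass(peak_dip_timing(st_sd, "peak"))[c("median", "p_sign", "n_excluded")],
        smpd_dip = unclass(peak_dip_timing(st_sd, "dip"))[c("median", "p_sign", "n_excluded")]))
  }
  map <- build_rate_map(occ, u, config$display_clip)
  pis <- place_info_significance(u, occ, config$n_shifts_place, "shift",
                                 config$min_shift, config$alpha,
                                 seed = unit_seed, min_spikes = config$min_spikes)
  out$place <- list(
    mean_rate = map$mean_rate, max_rate = map$max_rate,
    information = if (is.null(pis)) NA_real_ else pis$information,
    significant_shift = if (is.null(pis)) NA else pis$significant,
    p_perm_shift = if (is.null(pis)) NA_real_ else pis$p_perm,
    p_t_shift = if (is.null(pis)) NA_real_ else pis$p_t,
    stationarity_p = stationarity_check(u)$p_value)
  out$direction_preference <- as.numeric(direction_preference_index(u, labels))
  ego <- suppressMessages(
    accumulate_stlm_ptlm(raster, traj, u, config$downsample_dt,
                         config$egocentric_window, config$exclude_pct,
                         config$min_spikes))
  if (!is.null(ego)) {
    pref <- ap_lr_preference(ego, config$body_length)
    out$egocentric <- list(lr_index = pref$lr_index, ap_index = pref$ap_index,
                           magnitude = pref$magnitude, angle = pref$angle,
                           n_excluded = sum(ego$excluded))
  }
  out
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("session_report: %d unit(s), %d down-state interval(s)\n",
              length(x$units), nrow(x$down_states)))
  for (u in x$units) {
    if (isTRUE(u$skipped)) {
      cat(sprintf("  %s: skipped (%s)\n", u$unit_id, u$reason))
    } else {
      cat(sprintf("  %s: %d spikes, I = %.3f bits/spike%s, DPI = %+.3f\n",
                  u$unit_id, u$n_spikes, u$place$information,
                  if (isTRUE(u$place$significant_shift)) "*" else "",
                  u$direction_preference))
    }
  }
  invisible(x)
}

#' Write a session report to disk
#'
#' `report.json` holds the full machine-readable report (config and seed
#' echoed for reproducibility); `sta.csv` holds the tidy triggered-average
#' traces (`unit, variable, lag, mean, sem`).
#'
#' @param report a [run_session()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.de_class(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  rows <- list()
  for (u in report$units) {
    if (isTRUE(u$skipped) || is.null(u$sta)) next
    for (v in c("st_eodr", "st_speed", "st_smpd")) {
      s <- u$sta[[v]]
      rows[[length(rows) + 1L]] <-
        data.frame(unit = u$unit_id, variable = v, lag = s$lags,
                   mean = s$mean, sem = s$sem)
    }
  }
  if (length(rows))
    utils::write.csv(do.call(rbind, rows), file.path(dir, "sta.csv"),
                     row.names = FALSE)
  invisible(dir)
}

.de_class <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .de_class)
  } else if (is.factor(x)) as.character(x) else unclass(x)
}
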