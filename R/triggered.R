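#' Spike-triggered average of a behavioral covariate
#'
#' Averages snippets of a uniformly sampled series (instantaneous EOD rate,
#' swim speed, ...) in a window of `half_window` seconds on each side of every
#' spike (default +/- 4 s, an 8 s window). Spikes are aligned to the nearest
#' grid sample; spikes whose window crosses the trial boundary are dropped
#' (behavioral series are not circular). Units with fewer than `min_spikes`
#' eligible spikes are skipped with a message, returning `NULL`.
#'
#' @param series an `eod_rate_series` or `covariate_series`.
#' @param spikes a [spike_train()].
#' @param half_window half-width of the window (s), default 4.
#' @param min_spikes minimum eligible spikes (default 10).
#' @param keep_traces keep the per-spike snippet matrix (needed for the peak
#'   test and timing statistics; default TRUE).
#' @return `triggered_average`: `lags` (s), `mean`, `sem`, `n_spikes`,
#'   `window_means` (per-spike whole-window means) and optionally `traces`
#'   (n_spikes x n_lags), or `NULL` if too few spikes.
#' @export
spike_triggered_average <- function(series, spikes, half_window = 4,
                                    min_spikes = 10L, keep_traces = TRUE) {
  stopifnot(inherits(spikes, "spike_train"))
  s <- .series_values(series)
  L <- as.integer(round(half_window / s$dt))
  n <- length(s$values)
  idx <- .nearest_frame(spikes$spike_times, s$times[1], s$dt, n)
  eligible <- idx - L >= 1L & idx + L <= n
  idx <- idx[eligible]
  if (length(idx) < min_spikes) {
    message(sprintf("unit %s skipped: %d eligible spikes (< %d)",
                    spikes$unit_id, length(idx), min_spikes))
    return(NULL)
  }
  lagidx <- -L:L
  traces <- matrix(s$values[outer(idx, lagidx, "+")],
                   nrow = length(idx), ncol = length(lagidx))
  out <- list(lags = lagidx * s$dt,
              mean = colMeans(traces),
              sem = apply(traces, 2, stats::sd) / sqrt(nrow(traces)),
              n_spikes = nrow(traces),
              window_means = rowMeans(traces),
              dt = s$dt,
              unit_id = spikes$unit_id)
  if (keep_traces) out$traces <- traces
  structure(out, class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("triggered_average: %d spikes, lags %.2g..%.2g s, mean %.3g\n",
              x$n_spikes, min(x$lags), max(x$lags), mean(x$mean)))
  invisible(x)
}

#' Spike-triggered sampling density
#'
#' Sampling density (pulses emitted per cm traveled) is EOD rate divided by
#' swim speed; its spike-triggered average is computed by dividing the
#' per-spike EOD-rate snippet by the per-spike speed snippet elementwise and
#' then averaging — NOT by dividing the two mean traces. Speed is floored at
#' `speed_floor` before division to keep the quotient finite at quiescence
#' edges; spikes with an all-zero speed snippet are excluded and counted.
#'
#' @param steodr `triggered_average` of EOD rate (with traces).
#' @param stspeed `triggered_average` of speed for the same spikes (with
#'   traces).
#' @param speed_floor minimum speed used in the division (cm/s), default 0.5.
#' @return `triggered_average` of sampling density (pulses/cm) with an extra
#'   field `n_excluded`.
#' @export
st_sampling_density <- function(steodr, stspeed, speed_floor = 0.5) {
  stopifnot(inherits(steodr, "triggered_average"),
            inherits(stspeed, "triggered_average"))
  if (is.null(steodr$traces) || is.null(stspeed$traces))
    stop("per-spike traces are required (keep_traces = TRUE)")
  if (!identical(dim(steodr$traces), dim(stspeed$traces)) ||
      max(abs(steodr$lags - stspeed$lags)) > 1e-9)
    stop("stEODr and stSpeed must share spikes and lag grid")
  all_zero <- rowSums(stspeed$traces != 0) == 0L
  keep <- !all_zero
  if (!any(keep)) stop("no spikes with nonzero speed snippets")
  q <- steodr$traces[keep, , drop = FALSE] /
    pmax(stspeed$traces[keep, , drop = FALSE], speed_floor)
  structure(list(lags = steodr$lags,
                 mean = colMeans(q),
                 sem = apply(q, 2, stats::sd) / sqrt(nrow(q)),
                 n_spikes = nrow(q),
                 window_means = rowMeans(q),
                 dt = steodr$dt,
                 unit_id = steodr$unit_id,
                 traces = q,
                 n_excluded = sum(all_zero)),
            class = "triggered_average")
}

#' Circular-shift surrogate spike trains
#'
#' Each surrogate shifts the whole spike train by a random time drawn
#' uniformly from `[min_shift, trial_duration - min_shift]` (default at least
#' 30 s), wrapping modulo the trial duration. Shifting preserves the spike
#' count and the circular inter-spike-interval multiset, destroying only the
#' alignment between spikes and behavior.
#'
#' @param spikes a [spike_train()].
#' @param n_shifts number of surrogates (default 100).
#' @param min_shift minimum shift (s), default 30.
#' @param seed RNG seed for the shift draws.
#' @return `circular_shift_null`: `shifts` (s) and `trains` (list of
#'   [spike_train()]).
#' @export
circular_shift_null <- function(spikes, n_shifts = 100L, min_shift = 30,
                                seed = NULL) {
  stopifnot(inherits(spikes, "spike_train"))
  T <- spikes$trial_duration
  if (T <= 2 * min_shift)
    stop("trial too short for circular shifting (duration <= 2 * min_shift)")
  shifts <- with_seed(seed, stats::runif(n_shifts, min_shift, T - min_shift))
  trains <- lapply(shifts, function(s) shift_spike_train(spikes, s))
  structure(list(shifts = shifts, trains = trains, n_shifts = n_shifts,
                 min_shift = min_shift),
            class = "circular_shift_null")
}

#' Circularly shift one spike train
#'
#' @param spikes a [spike_train()].
#' @param shift shift (s); times wrap modulo the trial duration.
#' @return A [spike_train()].
#' @export
shift_spike_train <- function(spikes, shift) {
  t <- sort((spikes$spike_times + shift) %% spikes$trial_duration)
  spike_train(t, spikes$trial_duration, unit_id = spikes$unit_id,
              trial_id = spikes$trial_id)
}

#' Triggered averages for a surrogate ensemble
#'
#' @param series the covariate series.
#' @param null a [circular_shift_null()].
#' @param half_window,min_spikes,keep_traces as in
#'   [spike_triggered_average()]; traces are dropped by default to save
#'   memory.
#' @return list of `triggered_average` (surrogates with too few eligible
#'   spikes yield `NULL` entries).
#' @export
null_triggered_averages <- function(series, null, half_window = 4,
                                    min_spikes = 10L, keep_traces = FALSE) {
  stopifnot(inherits(null, "circular_shift_null"))
  lapply(null$trains, function(tr)
    suppressMessages(spike_triggered_average(series, tr, half_window,
                                             min_spikes, keep_traces)))
}

#' Kruskal-Wallis test for whole-window mean elevation
#'
#' Compares the per-spike whole-window means of the observed triggered
#' average against the pooled per-spike window means of the circular-shift
#' surrogates, asking whether the covariate around spikes is elevated (or
#' depressed) overall relative to chance alignment.
#'
#' @param observed the observed `triggered_average`.
#' @param null_averages list of surrogate `triggered_average`s
#'   ([null_triggered_averages()]).
#' @return list with `statistic` (H), `p_value`, `n_observed`, `n_null`.
#' @export
test_mean_elevation <- function(observed, null_averages) {
  stopifnot(inherits(observed, "triggered_average"))
  nullpool <- unlist(lapply(null_averages, function(a)
    if (is.null(a)) NULL else a$window_means))
  if (!length(nullpool)) stop("empty null ensemble")
  obs <- observed$window_means
  if (length(unique(c(obs, nullpool))) == 1L) {
    warning("degenerate data (all values tied); p = 1")
    return(list(statistic = 0, p_value = 1, n_observed = length(obs),
                n_null = length(nullpool)))
  }
  kw <- stats::kruskal.test(list(obs, nullpool))
  list(statistic = unname(kw$statistic), p_value = kw$p.value,
       n_observed = length(obs), n_null = length(nullpool))
}

#' Wilcoxon sign-rank test for a peak (or dip) in the average
#'
#' Locates the extremum of the mean triggered trace, takes each spike's value
#' at that lag and compares it with the same spike's whole-window mean by a
#' paired Wilcoxon sign-rank test (`greater` for peaks, `less` for dips).
#'
#' @param observed `triggered_average` with per-spike traces.
#' @param which `"peak"` (maximum of the mean trace) or `"dip"` (minimum).
#' @param min_spikes minimum number of pairs (default 10).
#' @return list with `p_value`, `statistic` (V), `extremum_lag` (s), `which`,
#'   or `NULL` if too few pairs.
#' @export
test_peak <- function(observed, which = c("peak", "dip"), min_spikes = 10L) {
  which <- match.arg(which)
  stopifnot(inherits(observed, "triggered_average"))
  if (is.null(observed$traces)) stop("per-spike traces required")
  if (observed$n_spikes < min_spikes) {
    message("too few spikes for the peak test")
    return(NULL)
  }
  i <- if (which == "peak") which.max(observed$mean) else which.min(observed$mean)
  vals <- observed$traces[, i]
  alt <- if (which == "peak") "greater" else "less"
  wt <- suppressWarnings(stats::wilcox.test(vals, observed$window_means,
                                            paired = TRUE, alternative = alt,
                                            exact = FALSE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       extremum_lag = observed$lags[i], which = which)
}

# interior local minima of one snippet, plateaus resolved to their center
# sample; returns lag index of the smallest local minimum (ties broken toward
# lag 0), or NA when no interior local minimum exists
.smallest_local_min <- function(x, lags) {
  r <- rle(x)
  nruns <- length(r$lengths)
  if (nruns < 3) return(NA_integer_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_idx <- integer(0); cand_val <- numeric(0)
  for (k in 2:(nruns - 1)) {
    if (r$values[k] < r$values[k - 1] && r$values[k] < r$values[k + 1]) {
      center <- (starts[k] + ends[k]) %/% 2L
      cand_idx <- c(cand_idx, center)
      cand_val <- c(cand_val, r$values[k])
    }
  }
  if (!length(cand_idx)) return(NA_integer_)
  best <- cand_idx[cand_val == min(cand_val)]
  best[which.min(abs(lags[best]))]
}

#' Per-spike peak and dip timing with a sign test on the median
#'
#' For each spike snippet, the peak time is the lag of the largest value
#' (ties resolved toward lag 0) and the dip time is the lag of the smallest
#' interior local minimum (strict-neighbor test, plateaus resolved to their
#' center sample, ties toward lag 0). Snippets with no interior local minimum
#' have an undefined dip and are excluded (and counted). A non-parametric
#' sign test asks whether the timing median differs from zero.
#'
#' @param observed `triggered_average` with per-spike traces.
#' @param mode `"peak"` or `"dip"`.
#' @return `peak_dip_timing`: `times` (s, per spike; `NA` = undefined),
#'   `median` (s), `p_sign`, `n_excluded`, `mode`.
#' @export
peak_dip_timing <- function(observed, mode = c("peak", "dip")) {
  mode <- match.arg(mode)
  stopifnot(inherits(observed, "triggered_average"))
  if (is.null(observed$traces)) stop("per-spike traces required")
  lags <- observed$lags
  times <- unname(apply(observed$traces, 1, function(x) {
    if (mode == "peak") {
      cands <- which(x == max(x))
      lags[cands[which.min(abs(lags[cands]))]]
    } else {
      i <- .smallest_local_min(x, lags)
      if (is.na(i)) NA_real_ else lags[i]
    }
  }))
  s <- times[!is.na(times) & times != 0]
  p <- if (length(s)) stats::binom.test(sum(s > 0), length(s))$p.value else NA_real_
  structure(list(times = times, median = stats::median(times, na.rm = TRUE),
                 p_sign = p, n_excluded = sum(is.na(times)), mode = mode),
            class = "peak_dip_timing")
}

#' @export
print.peak_dip_timing <- function(x, ...) {
  cat(sprintf("%s timing: median %+.3f s (sign test p = %.3g, %d/%d undefined)\n",
              x$mode, x$median, x$p_sign, x$n_excluded, length(x$times)))
  invisible(x)
}
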