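#' Occupancy grid with entry-based visit counting
#'
#' Divides the tank's bounding box into square bins (default 16 x 16 cm,
#' anchored at the bounding-box corner) and accumulates time spent and visit
#' counts per bin. A visit is counted when the head first arrives in a bin;
#' consecutive frames in the same bin still count as one visit, and the count
#' may only increase after the fish leaves and returns. Bins visited fewer
#' than `visit_min` times (default 5) are excluded from analysis; occupancy
#' probabilities `p` are normalized over the included bins.
#'
#' @param traj a [tracked_trajectory()].
#' @param arena an [arena_layout()].
#' @param bin_size bin edge length (cm), default 16.
#' @param visit_min minimum visits for inclusion (default 5).
#' @return `occupancy_grid`: bin edges/centers, per-bin `time` (s), `visits`,
#'   logical `included` and occupancy probability `p` (matrices nx x ny),
#'   plus the per-frame bin index used downstream.
#' @export
build_occupancy <- function(traj, arena, bin_size = 16, visit_min = 5L) {
  stopifnot(inherits(traj, "tracked_trajectory"), inherits(arena, "arena_layout"))
  .stopifnot_scalar_pos(bin_size, "bin_size")
  if (!length(traj$times)) stop("empty trajectory")
  x0 <- arena$tank_center[1] - arena$tank_radius
  y0 <- arena$tank_center[2] - arena$tank_radius
  nx <- as.integer(ceiling(2 * arena$tank_radius / bin_size))
  ny <- nx
  ex <- x0 + bin_size * (0:nx)
  ey <- y0 + bin_size * (0:ny)
  ix <- pmin(pmax(findInterval(traj$x, ex, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(traj$y, ey, rightmost.closed = TRUE), 1L), ny)
  bin <- (iy - 1L) * nx + ix
  nb <- nx * ny
  time <- tabulate(bin, nbins = nb) * traj$dt
  entries <- bin[c(TRUE, diff(bin) != 0L)]     # first frame + every bin change
  visits <- tabulate(entries, nbins = nb)
  included <- visits >= visit_min
  p <- rep(0, nb)
  tot <- sum(time[included])
  if (tot > 0) p[included] <- time[included] / tot
  structure(list(bin_size = bin_size, x_edges = ex, y_edges = ey,
                 x_centers = (ex[-1] + ex[-(nx + 1)]) / 2,
                 y_centers = (ey[-1] + ey[-(ny + 1)]) / 2,
                 nx = nx, ny = ny,
                 time = matrix(time, nx, ny),
                 visits = matrix(visits, nx, ny),
                 included = matrix(included, nx, ny),
                 p = matrix(p, nx, ny),
                 frame_bin = bin, dt = traj$dt,
                 t0 = traj$times[1], n_frames = length(traj$times),
                 visit_min = visit_min),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid: %d x %d bins of %g cm, %d included (>= %d visits)\n",
              x$nx, x$ny, x$bin_size, sum(x$included), x$visit_min))
  invisible(x)
}

# per-spike bin index via the nearest video frame
.spike_bins <- function(occ, spikes) {
  idx <- .nearest_frame(spikes$spike_times, occ$t0, occ$dt, occ$n_frames)
  occ$frame_bin[idx]
}

#' Spatial firing-rate map
#'
#' Each spike is assigned to the video frame nearest its time, and the rate
#' in a bin is the spike count divided by the time spent there. Rates are
#' reported for included bins only (`NA` elsewhere); a display copy is
#' clipped to the 97th percentile of the included-bin rates so that bins with
#' tiny occupancy do not saturate color plots. The occupancy-weighted mean
#' rate `r_m = sum(p_i r_i)` is stored alongside.
#'
#' @param occ an [build_occupancy()] result.
#' @param spikes a [spike_train()].
#' @param display_clip percentile for the clipped display copy (default 97).
#' @return `rate_map`: `rate` (Hz, nx x ny, NA at excluded bins),
#'   `rate_clipped`, `mean_rate` (r_m), `max_rate`, `n_spikes`.
#' @export
build_rate_map <- function(occ, spikes, display_clip = 97) {
  stopifnot(inherits(occ, "occupancy_grid"), inherits(spikes, "spike_train"))
  counts <- tabulate(.spike_bins(occ, spikes), nbins = occ$nx * occ$ny)
  counts <- matrix(counts, occ$nx, occ$ny)
  rate <- matrix(NA_real_, occ$nx, occ$ny)
  inc <- occ$included & occ$time > 0
  rate[inc] <- counts[inc] / occ$time[inc]
  r <- rate[inc]
  clip <- if (length(r)) stats::quantile(r, display_clip / 100, names = FALSE) else NA
  rate_clipped <- pmin(rate, clip)
  structure(list(rate = rate, rate_clipped = rate_clipped,
                 counts = counts,
                 mean_rate = sum(occ$p[inc] * rate[inc]),
                 max_rate = if (length(r)) max(r) else NA_real_,
                 display_clip = display_clip,
                 n_spikes = length(spikes$spike_times),
                 unit_id = spikes$unit_id),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("rate_map %s: %d spikes, mean %.3g Hz, max FR/bin %.3g Hz\n",
              x$unit_id, x$n_spikes, x$mean_rate, x$max_rate))
  invisible(x)
}

#' Skaggs spatial information
#'
#' Place information in bits per spike,
#' `I = sum_i p_i (r_i / r_m) log2(r_i / r_m)` over included bins, where `p_i`
#' is the occupancy probability, `r_i` the firing rate in bin i and `r_m` the
#' occupancy-weighted mean rate. Zero-rate bins contribute 0 (the
#' `x log x -> 0` limit).
#'
#' @param map a [build_rate_map()] result.
#' @param occ the matching occupancy grid.
#' @return information (bits/spike).
#' @export
place_information <- function(map, occ) {
  stopifnot(inherits(map, "rate_map"), inherits(occ, "occupancy_grid"))
  inc <- occ$included & occ$time > 0
  r <- map$rate[inc]; p <- occ$p[inc]
  rm_ <- sum(p * r)
  if (!is.finite(rm_) || rm_ <= 0) stop("mean rate is zero; information undefined")
  pos <- r > 0
  sum(p[pos] * (r[pos] / rm_) * log2(r[pos] / rm_))
}

#' Significance of place information by permutation
#'
#' Recomputes the spatial information for surrogate spike trains and asks
#' whether the observed value exceeds the 95th percentile of the surrogate
#' distribution. Two nulls are available: `"shift"` circularly time-shifts
#' the whole train (conserving relative spike timing; conservative, because
#' within-trial rate inhomogeneity survives the shift) and `"shuffle"` draws
#' spike times uniformly over the trial (liberal). A one-sample t-test of the
#' surrogate distribution against the observed value is also reported, as a
#' second, parametric criterion.
#'
#' @param spikes a [spike_train()].
#' @param occ occupancy grid for the trial (fixed across surrogates).
#' @param n_surrogates number of surrogates (default 1000).
#' @param method `"shift"` or `"shuffle"`.
#' @param min_shift minimum circular shift (s), default 30.
#' @param alpha significance level for the percentile criterion (default
#'   0.05, i.e. the 95th percentile).
#' @param seed RNG seed.
#' @param min_spikes minimum spike count (default 10); fewer returns `NULL`.
#' @return `place_info_result`: `information` (bits/spike), `null_info`
#'   (surrogate values), `percentile_crit` (the 1-alpha surrogate quantile),
#'   `significant`, `p_perm` (fraction of surrogates >= observed), `p_t`
#'   (t-test), `method`, `n_spikes`.
#' @export
place_info_significance <- function(spikes, occ, n_surrogates = 1000L,
                                    method = c("shift", "shuffle"),
                                    min_shift = 30, alpha = 0.05, seed = NULL,
                                    min_spikes = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(spikes, "spike_train"), inherits(occ, "occupancy_grid"))
  n <- length(spikes$spike_times)
  if (n < min_spikes) {
    message(sprintf("unit %s skipped: %d spikes (< %d)", spikes$unit_id, n,
                    min_spikes))
    return(NULL)
  }
  T <- spikes$trial_duration
  inc <- occ$included & occ$time > 0
  p <- occ$p[inc]; tm <- occ$time[inc]
  info_from_counts <- function(counts) {
    r <- counts[inc] / tm
    rm_ <- sum(p * r)
    if (rm_ <= 0) return(NA_real_)
    pos <- r > 0
    sum(p[pos] * (r[pos] / rm_) * log2(r[pos] / rm_))
  }
  nb <- occ$nx * occ$ny
  obs <- info_from_counts(matrix(tabulate(.spike_bins(occ, spikes), nbins = nb),
                                 occ$nx, occ$ny))
  null_info <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(k) {
      t_surr <- if (method == "shift")
        (spikes$spike_times + stats::runif(1, min_shift, T - min_shift)) %% T
      else stats::runif(n, 0, T)
      idx <- .nearest_frame(t_surr, occ$t0, occ$dt, occ$n_frames)
      info_from_counts(matrix(tabulate(occ$frame_bin[idx], nbins = nb),
                              occ$nx, occ$ny))
    }, numeric(1))
  })
  null_info <- null_info[is.finite(null_info)]
  crit <- stats::quantile(null_info, 1 - alpha, names = FALSE)
  tt <- stats::t.test(null_info, mu = obs, alternative = "less")
  structure(list(information = obs, null_info = null_info,
                 percentile_crit = crit, significant = obs > crit,
                 p_perm = (sum(null_info >= obs) + 1) / (length(null_info) + 1),
                 p_t = tt$p.value, method = method, n_spikes = n),
            class = "place_info_result")
}

#' @export
print.place_info_result <- function(x, ...) {
  cat(sprintf("place information: %.3f bits/spike (%s null, %s; perm p = %.3g)\n",
              x$information, x$method,
              if (x$significant) "significant" else "not significant", x$p_perm))
  invisible(x)
}

#' Within-trial firing-rate stationarity check
#'
#' Splits a trial in two halves, computes the firing rate in 5 equal time
#' bins per half, and compares the two sets of five values with a
#' Kruskal-Wallis test. Significant inhomogeneity means circular time
#' shifting is not an appropriate null for that trial.
#'
#' @param spikes a [spike_train()].
#' @param n_bins_per_half bins per half (default 5).
#' @return list with `p_value`, `statistic`, `rates` (length 10), `edges`.
#' @export
stationarity_check <- function(spikes, n_bins_per_half = 5L) {
  stopifnot(inherits(spikes, "spike_train"))
  T <- spikes$trial_duration
  nb <- 2L * n_bins_per_half
  edges <- seq(0, T, length.out = nb + 1)
  counts <- tabulate(findInterval(spikes$spike_times, edges,
                                  rightmost.closed = TRUE), nbins = nb)
  rates <- counts / diff(edges)
  grp <- rep(1:2, each = n_bins_per_half)
  if (length(unique(rates)) == 1L)
    return(list(p_value = 1, statistic = 0, rates = rates, edges = edges))
  kw <- stats::kruskal.test(rates, factor(grp))
  list(p_value = kw$p.value, statistic = unname(kw$statistic), rates = rates,
       edges = edges)
}

#' Cross-trial firing-rate comparison
#'
#' Compares firing rates over 10 equal time bins in each of two trials of the
#' same unit with a Kruskal-Wallis test.
#'
#' @param spikes_a,spikes_b [spike_train()]s from consecutive trials.
#' @param n_bins bins per trial (default 10).
#' @return list with `p_value`, `statistic`, `rates_a`, `rates_b`.
#' @export
cross_trial_stationarity <- function(spikes_a, spikes_b, n_bins = 10L) {
  rate_bins <- function(sp) {
    edges <- seq(0, sp$trial_duration, length.out = n_bins + 1)
    tabulate(findInterval(sp$spike_times, edges, rightmost.closed = TRUE),
             nbins = n_bins) / diff(edges)
  }
  ra <- rate_bins(spikes_a); rb <- rate_bins(spikes_b)
  if (length(unique(c(ra, rb))) == 1L)
    return(list(p_value = 1, statistic = 0, rates_a = ra, rates_b = rb))
  kw <- stats::kruskal.test(c(ra, rb), factor(rep(1:2, each = n_bins)))
  list(p_value = kw$p.value, statistic = unname(kw$statistic),
       rates_a = ra, rates_b = rb)
}

#' Effect of removing a landmark on nearby firing
#'
#' Compares the average firing rate over bins whose centers lie within
#' `radius` cm of the landmark polygon boundary (distance 0 inside the
#' polygon), before and after the landmark's removal. Rates are also
#' normalized by the larger of the two means so effects pool across
#' landmarks/units.
#'
#' @param map_before,map_after [build_rate_map()] results for the two
#'   conditions (same binning).
#' @param occ_before,occ_after matching occupancy grids.
#' @param landmark polygon (n x 2 matrix, cm).
#' @param radius disc radius (cm), default 10.
#' @return `landmark_effect`: `mean_before`, `mean_after`, `ratio`
#'   (after/before), `norm_before`, `norm_after`, `n_bins`, `bins` (logical
#'   disc-membership matrix).
#' @export
landmark_removal_effect <- function(map_before, map_after, occ_before,
                                    occ_after, landmark, radius = 10) {
  stopifnot(inherits(map_before, "rate_map"), inherits(map_after, "rate_map"))
  if (occ_before$nx != occ_after$nx || occ_before$ny != occ_after$ny ||
      occ_before$bin_size != occ_after$bin_size)
    stop("the two conditions must share the same binning")
  landmark <- .as_polygon(landmark)
  cx <- rep(occ_before$x_centers, times = occ_before$ny)
  cy <- rep(occ_before$y_centers, each = occ_before$nx)
  disc <- matrix(.dist_poly(cx, cy, landmark) <= radius,
                 occ_before$nx, occ_before$ny)
  sel_b <- disc & occ_before$included & is.finite(map_before$rate)
  sel_a <- disc & occ_after$included & is.finite(map_after$rate)
  if (!any(sel_b) || !any(sel_a))
    stop("no included bins within the radius in one of the conditions")
  mb <- mean(map_before$rate[sel_b])
  ma <- mean(map_after$rate[sel_a])
  mx <- max(mb, ma)
  structure(list(mean_before = mb, mean_after = ma,
                 ratio = if (mb > 0) ma / mb else NA_real_,
                 norm_before = if (mx > 0) mb / mx else NA_real_,
                 norm_after = if (mx > 0) ma / mx else NA_real_,
                 n_bins = c(before = sum(sel_b), after = sum(sel_a)),
                 bins = disc),
            class = "landmark_effect")
}

#' Pooled test of landmark-removal effects
#'
#' Kruskal-Wallis test comparing the normalized near-landmark firing rates
#' before vs after removal, pooled over a set of landmark/unit effects.
#'
#' @param effects list of [landmark_removal_effect()] results.
#' @return list with `p_value`, `statistic`, `n`, and the pooled normalized
#'   rates.
#' @export
landmark_effect_test <- function(effects) {
  nb <- vapply(effects, function(e) e$norm_before, numeric(1))
  na_ <- vapply(effects, function(e) e$norm_after, numeric(1))
  ok <- is.finite(nb) & is.finite(na_)
  nb <- nb[ok]; na_ <- na_[ok]
  if (length(unique(c(nb, na_))) == 1L)
    return(list(p_value = 1, statistic = 0, n = length(nb),
                norm_before = nb, norm_after = na_))
  kw <- stats::kruskal.test(c(nb, na_),
                            factor(rep(c("before", "after"), c(length(nb), length(na_)))))
  list(p_value = kw$p.value, statistic = unname(kw$statistic), n = length(nb),
       norm_before = nb, norm_after = na_)
}
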