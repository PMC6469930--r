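make_series <- function(values, dt = 1 / 15) {
  covariate_series((seq_along(values) - 1) * dt, values)
}

test_that("constant series yields a constant mean with zero SEM", {
  s <- make_series(rep(7, 1500))
  sp <- spike_train(seq(10, 90, by = 5), 100)
  ta <- spike_triggered_average(s, sp)
  expect_equal(ta$mean, rep(7, length(ta$lags)))
  expect_equal(ta$sem, rep(0, length(ta$lags)))
  expect_equal(range(ta$lags), c(-4, 4), tolerance = 1e-9)
})

test_that("a single spike on a lag-locked bump returns the bump itself", {
  dt <- 1 / 15
  n <- 1500
  v <- rep(0, n)
  spike_t <- 50
  k0 <- round(spike_t / dt) + 1
  bump_at <- k0 + 3                      # bump 0.2 s after the spike
  v[bump_at] <- 5
  ta <- spike_triggered_average(make_series(v, dt),
                                spike_train(spike_t, 100), min_spikes = 1)
  expect_equal(ta$n_spikes, 1L)
  expect_equal(ta$mean[which.max(ta$mean)], 5)
  expect_equal(ta$lags[which.max(ta$mean)], 3 * dt, tolerance = 1e-9)
})

test_that("triggered average equals a brute-force snippet loop", {
  set.seed(51)
  dt <- 1 / 15
  v <- cumsum(rnorm(3000)) + 60
  sp_t <- sort(runif(40, 10, 190))
  sp <- spike_train(sp_t, 200)
  ta <- spike_triggered_average(make_series(v, dt), sp)
  L <- round(4 / dt)
  # oracle: explicit loop over spikes, nearest-sample alignment
  keep <- vapply(sp_t, function(t) {
    i <- round(t / dt) + 1
    i - L >= 1 && i + L <= length(v)
  }, logical(1))
  snippets <- t(vapply(sp_t[keep], function(t) {
    i <- round(t / dt) + 1
    v[(i - L):(i + L)]
  }, numeric(2 * L + 1)))
  expect_equal(ta$n_spikes, sum(keep))
  expect_equal(ta$mean, colMeans(snippets), tolerance = 1e-12)
  expect_equal(ta$sem, apply(snippets, 2, sd) / sqrt(nrow(snippets)),
               tolerance = 1e-12)
})

test_that("spikes whose window crosses the trial edges are dropped", {
  s <- make_series(rep(1, 300))   # 20 s of data
  sp <- spike_train(c(1, 10, 19), 20)
  ta <- spike_triggered_average(s, sp, min_spikes = 1)
  expect_equal(ta$n_spikes, 1L)   # only the 10 s spike has a full +/-4 s window
  expect_message(
    expect_null(spike_triggered_average(s, spike_train(c(1, 19), 20))),
    "skipped")
})

test_that("sampling density is the mean of per-spike quotients", {
  # constant EODr 60 Hz over speed 10 cm/s -> 6 pulses/cm
  e <- make_series(rep(60, 1500))
  v <- make_series(rep(10, 1500))
  sp <- spike_train(seq(10, 90, by = 4), 100)
  smpd <- st_sampling_density(spike_triggered_average(e, sp),
                              spike_triggered_average(v, sp))
  expect_equal(smpd$mean, rep(6, length(smpd$lags)))

  # 50 / 50 -> 1 pulse/cm
  e2 <- make_series(rep(50, 1500)); v2 <- make_series(rep(50, 1500))
  smpd2 <- st_sampling_density(spike_triggered_average(e2, sp),
                               spike_triggered_average(v2, sp))
  expect_equal(smpd2$mean, rep(1, length(smpd2$lags)))

  # random snippets: elementwise quotient oracle (not quotient of means)
  set.seed(52)
  ev <- runif(3000, 40, 100)
  vv <- runif(3000, 2, 20)
  spr <- spike_train(sort(runif(30, 10, 190)), 200)
  ta_e <- spike_triggered_average(make_series(ev), spr)
  ta_v <- spike_triggered_average(make_series(vv), spr)
  smpd3 <- st_sampling_density(ta_e, ta_v, speed_floor = 0.5)
  oracle <- colMeans(ta_e$traces / pmax(ta_v$traces, 0.5))
  expect_equal(smpd3$mean, oracle, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(smpd3$mean, ta_e$mean / ta_v$mean)))
})

test_that("circular shifting preserves count and circular ISI multiset", {
  set.seed(53)
  sp <- spike_train(sort(runif(100, 0, 600)), 600)
  null <- circular_shift_null(sp, n_shifts = 20, seed = 54)
  circ_isi <- function(t, T) sort(diff(c(t, t[1] + T)))
  base <- circ_isi(sp$spike_times, 600)
  for (tr in null$trains) {
    expect_equal(length(tr$spike_times), 100L)
    expect_equal(circ_isi(tr$spike_times, 600), base, tolerance = 1e-9)
  }
  expect_true(all(null$shifts >= 30 & null$shifts <= 570))

  # shifting by T/2 twice recovers the original train
  twice <- shift_spike_train(shift_spike_train(sp, 300), 300)
  expect_equal(twice$spike_times, sp$spike_times, tolerance = 1e-9)

  # trial too short to shift
  expect_error(circular_shift_null(spike_train(c(1, 2), 50), n_shifts = 5),
               "too short")
})

test_that("mean-elevation test is null-consistent and detects coupling", {
  set.seed(55)
  # null-consistent: observed spikes share the surrogates' distribution
  v <- 60 + 5 * sin(seq(0, 120 * pi, length.out = 9000))
  s <- make_series(v)
  sp <- spike_train(sort(runif(80, 10, 590)), 600)
  null <- circular_shift_null(sp, n_shifts = 50, seed = 56)
  nta <- null_triggered_averages(s, null)
  res <- test_mean_elevation(spike_triggered_average(s, sp), nta)
  expect_gt(res$p_value, 0.05)

  # strong elevation: spikes placed where the covariate is high
  high <- which(v > 64)
  sp2 <- spike_train(sort(sample(high, 60)) / 15, 600)
  null2 <- circular_shift_null(sp2, n_shifts = 50, seed = 57)
  res2 <- test_mean_elevation(spike_triggered_average(s, sp2),
                              null_triggered_averages(s, null2))
  expect_lt(res2$p_value, 0.001)

  # degenerate all-tied data
  flat <- make_series(rep(3, 9000))
  expect_warning(
    r3 <- test_mean_elevation(spike_triggered_average(flat, sp),
                              null_triggered_averages(flat, null)),
    "degenerate")
  expect_equal(r3$p_value, 1)
})

test_that("peak test finds injected post-spike bumps, flat series do not alarm", {
  set.seed(58)
  dt <- 1 / 15
  n <- 9000
  sp_t <- sort(runif(60, 10, 590))
  idx <- round(sp_t / dt) + 1
  # post-spike bump 0.2 s (3 frames) after each spike
  v <- rnorm(n, 10, 0.5)
  for (i in idx) v[(i + 2):(i + 4)] <- v[(i + 2):(i + 4)] + 4
  ta <- spike_triggered_average(make_series(v, dt), spike_train(sp_t, 600))
  res <- test_peak(ta, "peak")
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$extremum_lag, 0)
  # the injected bump spans lags 0.13-0.27 s
  expect_true(res$extremum_lag >= 0.1 && res$extremum_lag <= 0.3)

  # pre-spike bump -> negative lag
  v2 <- rnorm(n, 10, 0.5)
  for (i in idx) v2[(i - 8):(i - 6)] <- v2[(i - 8):(i - 6)] + 4
  ta2 <- spike_triggered_average(make_series(v2, dt), spike_train(sp_t, 600))
  res2 <- test_peak(ta2, "peak")
  expect_lt(res2$p_value, 1e-4)
  expect_lt(res2$extremum_lag, 0)
})

test_that("peak and dip timing statistics follow snippet geometry", {
  dt <- 1 / 15
  L <- round(4 / dt)
  lags <- (-L:L) * dt
  bump <- function(at, sign = 1) {
    x <- rep(10, length(lags))
    i <- which.min(abs(lags - at))
    x[i] <- x[i] + sign * 3
    x
  }
  traces <- rbind(bump(0.2), bump(0.2), bump(0.2))
  ta <- structure(list(lags = lags, mean = colMeans(traces),
                       traces = traces, n_spikes = 3), class = "triggered_average")
  pt <- peak_dip_timing(ta, "peak")
  expect_equal(pt$median, 0.2, tolerance = dt)

  # V-shaped snippet with minimum at -0.5 s
  vshape <- 10 + abs(lags + 0.5)
  ta2 <- structure(list(lags = lags, mean = vshape,
                        traces = rbind(vshape, vshape), n_spikes = 2),
                   class = "triggered_average")
  dp <- peak_dip_timing(ta2, "dip")
  expect_equal(dp$median, -0.5, tolerance = dt)

  # monotonic snippet: no interior local minimum -> excluded and counted
  mono <- seq_along(lags) + 0
  ta3 <- structure(list(lags = lags, mean = mono, traces = rbind(mono),
                        n_spikes = 1), class = "triggered_average")
  dp3 <- peak_dip_timing(ta3, "dip")
  expect_true(is.na(dp3$times[1]))
  expect_equal(dp3$n_excluded, 1L)

  # plateau dip resolves to the center sample
  plat <- rep(10, length(lags)); plat[40:44] <- 4
  ta4 <- structure(list(lags = lags, mean = plat, traces = rbind(plat),
                        n_spikes = 1), class = "triggered_average")
  dp4 <- peak_dip_timing(ta4, "dip")
  expect_equal(dp4$times[1], lags[42], tolerance = 1e-9)
})

test_that("generator timing is recovered: pre-spike dip median within 0.2 s", {
  set.seed(59)
  dt <- 1 / 15
  n <- 27000
  sp_t <- sort(runif(150, 10, n * dt - 10))
  idx <- round(sp_t / dt) + 1
  # smooth pre-spike trough centred at -0.5 s in an otherwise noisy series
  v <- rnorm(n, 12, 0.3)
  trough <- -3 * exp(-((-15:15) * dt + 0.5)^2 / (2 * 0.15^2))
  for (i in idx) {
    w <- (i - 15):(i + 15)
    v[w] <- v[w] + trough
  }
  ta <- spike_triggered_average(make_series(v, dt),
                                spike_train(sp_t, n * dt))
  dp <- peak_dip_timing(ta, "dip")
  expect_lt(abs(dp$median - (-0.5)), 0.2)
  expect_lt(dp$p_sign, 0.01)   # dips significantly before the spike
})
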