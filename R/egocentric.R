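#' Swim-direction preference index
#'
#' `(FR_forward - FR_backward) / (FR_forward + FR_backward)` where each rate
#' is the number of spikes emitted in that swim state divided by the total
#' time spent in it (turns are pooled with the swim state of matching sign;
#' see [classify_swim_direction()]). Negative values mean a preference for
#' spiking during backward swims; the bounds +/-1 mean spiking exclusively
#' during forward/backward swimming.
#'
#' @param spikes a [spike_train()].
#' @param labels a `swim_labels` object for the same trial.
#' @return index in `[-1, 1]`; `NA` (with attribute `reason`) when the trial
#'   has no time in one of the states or no spikes while swimming.
#' @export
direction_preference_index <- function(spikes, labels) {
  stopifnot(inherits(spikes, "spike_train"), inherits(labels, "swim_labels"))
  t_f <- sum(labels$labels == "forward") * labels$dt
  t_b <- sum(labels$labels == "backward") * labels$dt
  if (t_f == 0 || t_b == 0)
    return(structure(NA_real_, reason = "no time in one swim state"))
  idx <- .nearest_frame(spikes$spike_times, labels$times[1], labels$dt,
                        length(labels$labels))
  st <- labels$labels[idx]
  fr_f <- sum(st == "forward") / t_f
  fr_b <- sum(st == "backward") / t_b
  if (fr_f + fr_b == 0)
    return(structure(NA_real_, reason = "no spikes during swimming"))
  (fr_f - fr_b) / (fr_f + fr_b)
}

#' Binary landmark raster of the arena
#'
#' A 160 x 120 element matrix covering the video frame (each element spans
#' `element_px` = 10 x 10 video pixels); elements containing a landmark, the
#' home, or the tank boundary are 1, all others 0. Element (i, j) covers the
#' world square `[(i-1) s, i s) x [(j-1) s, j s)` cm where
#' `s = element_px * pixel_scale`.
#'
#' @param arena an [arena_layout()].
#' @param element_px element edge in video pixels (default 10).
#' @return `landmark_raster`: a 0/1 matrix with attributes `element_cm`
#'   (element edge in cm) and `arena`.
#' @export
rasterize_arena <- function(arena, element_px = 10) {
  stopifnot(inherits(arena, "arena_layout"))
  nx <- as.integer(arena$video_size[1] / element_px)
  ny <- as.integer(arena$video_size[2] / element_px)
  el <- element_px * arena$pixel_scale
  cx <- (seq_len(nx) - 0.5) * el
  cy <- (seq_len(ny) - 0.5) * el
  gx <- rep(cx, times = ny)
  gy <- rep(cy, each = nx)
  val <- rep(FALSE, nx * ny)
  polys <- arena$landmarks
  if (!is.null(arena$home)) polys <- c(polys, list(arena$home))
  for (p in polys) val <- val | .in_poly(gx, gy, p)
  # tank boundary: elements whose center lies within half an element of the circle
  dring <- abs(sqrt((gx - arena$tank_center[1])^2 + (gy - arena$tank_center[2])^2) -
                 arena$tank_radius)
  val <- val | dring <= el / 2
  m <- matrix(as.numeric(val), nx, ny)
  attr(m, "element_cm") <- el
  attr(m, "arena") <- arena
  class(m) <- c("landmark_raster", class(m))
  m
}

#' Egocentric transform of the landmark raster
#'
#' Rotates and translates the allocentric raster so that the fish's position
#' lands on the center element and its heading points "north" (+y of the
#' output). Nearest-neighbor (containing-element) resampling preserves the
#' 0/1 semantics; output elements whose source falls outside the frame are
#' `NA` (invalid) and excluded from downstream sums.
#'
#' @param raster a [rasterize_arena()] result (or any matrix with an
#'   `element_cm` attribute).
#' @param position fish head position, `c(x, y)` cm.
#' @param heading body-axis direction (radians, from +x CCW).
#' @return matrix of the same shape; `NA` marks invalid elements. The output
#'   x axis is the fish's right, the y axis its anterior direction.
#' @export
egocentric_transform <- function(raster, position, heading) {
  el <- attr(raster, "element_cm")
  if (is.null(el)) stop("raster lacks an 'element_cm' attribute")
  n <- dim(raster)
  cx <- n[1] %/% 2L + 1L
  cy <- n[2] %/% 2L + 1L
  dx <- (seq_len(n[1]) - cx) * el     # egocentric right (+) / left (-)
  dy <- (seq_len(n[2]) - cy) * el     # egocentric anterior (+) / posterior (-)
  a <- c(cos(heading), sin(heading))  # world unit vector ahead
  r <- c(sin(heading), -cos(heading)) # world unit vector to the fish's right
  wx <- position[1] + outer(dx * r[1], dy * a[1], "+")
  wy <- position[2] + outer(dx * r[2], dy * a[2], "+")
  sx <- floor(wx / el) + 1
  sy <- floor(wy / el) + 1
  ok <- sx >= 1 & sx <= n[1] & sy >= 1 & sy <= n[2]
  out <- matrix(NA_real_, n[1], n[2])
  out[ok] <- unclass(raster)[cbind(as.integer(sx[ok]), as.integer(sy[ok]))]
  attr(out, "element_cm") <- el
  attr(out, "center") <- c(cx, cy)
  out
}

#' Spike- and position-triggered landmark matrices
#'
#' Accumulates the egocentrically transformed landmark raster at the pose of
#' every spike (STLM) and at regularly downsampled trajectory poses (PTLM;
#' every 1.33 s, i.e. every 20th frame at 15 Hz). The landmark-presence
#' probability given a spike is the elementwise STLM/PTLM quotient (computed
#' on per-element means so that invalid, out-of-frame elements are excluded
#' rather than diluting the sums), masked where the PTLM is zero or below its
#' lower 10th percentile, cropped to a square window extending `window_cm`
#' around the fish, and normalized to its maximum.
#'
#' @param raster a [rasterize_arena()] result.
#' @param traj a [tracked_trajectory()].
#' @param spikes a [spike_train()].
#' @param downsample_dt PTLM sampling period (s), default 1.33.
#' @param window_cm half-width of the egocentric analysis window (cm),
#'   default 10.
#' @param exclude_pct lower-percentile PTLM exclusion (default 10).
#' @param min_spikes minimum spikes (default 10); fewer returns `NULL`.
#' @return `egocentric_map`: `stlm`, `ptlm` (per-element mean matrices),
#'   `probability` (cropped, masked, max-normalized), `dx`, `dy` (egocentric
#'   offsets of the window elements, cm), `excluded` (logical mask on the
#'   window), `n_spikes`, `n_poses`.
#' @export
accumulate_stlm_ptlm <- function(raster, traj, spikes, downsample_dt = 1.33,
                                 window_cm = 10, exclude_pct = 10,
                                 min_spikes = 10L) {
  stopifnot(inherits(traj, "tracked_trajectory"), inherits(spikes, "spike_train"))
  el <- attr(raster, "element_cm")
  n <- dim(raster)
  if (length(spikes$spike_times) < min_spikes) {
    message(sprintf("unit %s skipped: fewer than %d spikes", spikes$unit_id,
                    min_spikes))
    return(NULL)
  }
  accumulate <- function(frames) {
    s <- matrix(0, n[1], n[2]); cnt <- matrix(0L, n[1], n[2])
    for (f in frames) {
      tr <- egocentric_transform(raster, c(traj$x[f], traj$y[f]), traj$heading[f])
      ok <- !is.na(tr)
      s[ok] <- s[ok] + tr[ok]
      cnt[ok] <- cnt[ok] + 1L
    }
    mean_ <- matrix(NA_real_, n[1], n[2])
    mean_[cnt > 0] <- s[cnt > 0] / cnt[cnt > 0]
    list(mean = mean_, count = cnt)
  }
  nf <- length(traj$times)
  spike_frames <- .nearest_frame(spikes$spike_times, traj$times[1], traj$dt, nf)
  step <- max(1L, as.integer(round(downsample_dt / traj$dt)))
  pose_frames <- seq(1L, nf, by = step)
  stlm <- accumulate(spike_frames)
  ptlm <- accumulate(pose_frames)
  prob_full <- stlm$mean / ptlm$mean
  # exclusion threshold from all finite PTLM elements (before cropping)
  pt <- ptlm$mean[is.finite(ptlm$mean)]
  thr <- stats::quantile(pt[pt > 0], exclude_pct / 100, names = FALSE)
  excluded_full <- !is.finite(ptlm$mean) | ptlm$mean <= 0 | ptlm$mean < thr
  prob_full[excluded_full] <- NA_real_
  # crop to the egocentric window
  cx <- n[1] %/% 2L + 1L; cy <- n[2] %/% 2L + 1L
  hw <- as.integer(floor(window_cm / el))
  wx <- (cx - hw):(cx + hw); wy <- (cy - hw):(cy + hw)
  prob <- prob_full[wx, wy]
  mx <- suppressWarnings(max(prob, na.rm = TRUE))
  if (is.finite(mx) && mx > 0) prob <- prob / mx
  structure(list(stlm = stlm$mean, ptlm = ptlm$mean, probability = prob,
                 dx = (wx - cx) * el, dy = (wy - cy) * el,
                 excluded = excluded_full[wx, wy],
                 element_cm = el, n_spikes = length(spike_frames),
                 n_poses = length(pose_frames), unit_id = spikes$unit_id),
            class = "egocentric_map")
}

#' @export
print.egocentric_map <- function(x, ...) {
  cat(sprintf("egocentric_map %s: %d spikes / %d poses, %dx%d window, %d excluded\n",
              x$unit_id, x$n_spikes, x$n_poses, length(x$dx), length(x$dy),
              sum(x$excluded)))
  invisible(x)
}

#' Anterior-posterior and left-right landmark preference
#'
#' Splits the egocentric window into four regions — left/right of the body
#' midline, each split at the boundary between the anterior 1/3 and posterior
#' 2/3 of the body (one third of a body length behind the tracked head point,
#' the zero of the A/P axis) — and forms preference indices from the maximum
#' landmark-presence probability per region:
#' `lr = (maxR - maxL) / (maxR + maxL)` and
#' `ap = (maxA - maxP) / (maxA + maxP)`, so positive values mean
#' right / anterior. Elements exactly on a boundary belong to neither side.
#'
#' @param map an [accumulate_stlm_ptlm()] result.
#' @param body_length fish body length (cm), default 15.
#' @return `preference_vector`: `lr_index`, `ap_index`, `magnitude`, `angle`
#'   (radians, `atan2(ap, lr)`), and the per-region maxima.
#' @export
ap_lr_preference <- function(map, body_length = 15) {
  stopifnot(inherits(map, "egocentric_map"))
  y0 <- -body_length / 3
  P <- map$probability
  dxg <- matrix(map$dx, length(map$dx), length(map$dy))
  dyg <- matrix(map$dy, length(map$dx), length(map$dy), byrow = TRUE)
  region_max <- function(sel) {
    v <- P[sel & !is.na(P)]
    if (!length(v)) NA_real_ else max(v)
  }
  maxR <- region_max(dxg > 0)
  maxL <- region_max(dxg < 0)
  maxA <- region_max(dyg > y0 + 1e-9)
  maxP <- region_max(dyg < y0 - 1e-9)
  idx <- function(a, b) {
    if (!is.finite(a) || !is.finite(b) || a + b == 0) NA_real_
    else (a - b) / (a + b)
  }
  lr <- idx(maxR, maxL)
  ap <- idx(maxA, maxP)
  structure(list(lr_index = lr, ap_index = ap,
                 magnitude = sqrt(lr^2 + ap^2), angle = atan2(ap, lr),
                 max_right = maxR, max_left = maxL,
                 max_anterior = maxA, max_posterior = maxP,
                 body_length = body_length),
            class = "preference_vector")
}

#' @export
print.preference_vector <- function(x, ...) {
  cat(sprintf("preference_vector: LR %+0.3f, AP %+0.3f (|v| = %.3f)\n",
              x$lr_index, x$ap_index, x$magnitude))
  invisible(x)
}
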