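# internal helpers shared across modules

# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# uniform grid step with a tolerance check
.grid_dt <- function(times, tol = 1e-6) {
  d <- diff(times)
  if (length(d) == 0L) stop("need at least two time points")
  dt <- stats::median(d)
  if (any(abs(d - dt) > tol * max(1, dt)))
    stop("time grid is not uniform")
  dt
}

# index of the grid sample nearest to each t (ties resolved toward the
# earlier sample); grid assumed uniform starting at t0 with step dt
.nearest_frame <- function(t, t0, dt, n) {
  u <- (t - t0) / dt
  frac <- u - floor(u)
  i <- ifelse(frac > 0.5 + 1e-9, ceiling(u), floor(u)) + 1
  pmin(pmax(as.integer(round(i)), 1L), n)
}

.wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi)
  a[a <= 0] <- a[a <= 0] + 2 * pi
  a - pi
}

.stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name))
}
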