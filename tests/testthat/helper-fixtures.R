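# shared fixtures, all built in code

# small arena for fast tests: 1.5 m tank, one square landmark + home
test_arena <- function() {
  arena_layout(tank_center = c(100, 75), tank_radius = 75,
               landmarks = list(block = cbind(c(120, 135, 135, 120),
                                              c(95, 95, 110, 110))),
               home = cbind(c(45, 65, 65, 45), c(60, 60, 80, 80)),
               pixel_scale = 0.125, video_size = c(1600, 1200))
}

# deterministic straight-line trajectory
line_trajectory <- function(n = 100, speed = 10, frame_rate = 15,
                            start = c(40, 75), heading = 0) {
  dt <- 1 / frame_rate
  t <- (seq_len(n) - 1) * dt
  tracked_trajectory(t,
                     start[1] + speed * t * cos(heading),
                     start[2] + speed * t * sin(heading),
                     rep(heading, n))
}

# stationary trajectory at a point
sit_trajectory <- function(n = 50, at = c(100, 75), frame_rate = 15) {
  t <- (seq_len(n) - 1) / frame_rate
  tracked_trajectory(t, rep(at[1], n), rep(at[2], n), rep(0, n))
}

# a tiny raster with a known element size for transform tests
toy_raster <- function(nx = 40, ny = 30, el = 1) {
  m <- matrix(0, nx, ny)
  attr(m, "element_cm") <- el
  m
}
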