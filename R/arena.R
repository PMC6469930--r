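#' Arena layout for a circular experimental tank with landmarks
#'
#' Describes the geometry of the recording arena: a circular tank viewed from
#' above by a fixed camera, with polygonal landmarks fixed to the tank floor
#' and an optional "home" structure the fish can enter. All coordinates are in
#' centimetres in the camera frame (x to the right, y up, origin at the frame
#' corner); `pixel_scale` converts video pixels to centimetres.
#'
#' @param tank_center numeric length-2, tank centre (cm).
#' @param tank_radius tank radius in cm (default 75, a 1.5 m tank).
#' @param landmarks named list of polygons, each an n x 2 matrix of vertex
#'   coordinates (cm). Landmarks are solid: the fish cannot enter them.
#' @param home optional polygon (n x 2 matrix) for the enterable home
#'   structure.
#' @param pixel_scale cm per video pixel (> 0).
#' @param video_size video frame size in pixels, `c(width, height)`.
#' @return An object of class `arena_layout`.
#' @examples
#' a <- default_arena()
#' print(a)
#' @export
arena_layout <- function(tank_center = c(100, 75), tank_radius = 75,
                         landmarks = list(), home = NULL,
                         pixel_scale = 0.125, video_size = c(1600, 1200)) {
  .stopifnot_scalar_pos(tank_radius, "tank_radius")
  .stopifnot_scalar_pos(pixel_scale, "pixel_scale")
  stopifnot(length(tank_center) == 2, length(video_size) == 2)
  if (length(landmarks)) {
    nm <- names(landmarks)
    if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
      stop("landmarks must have unique non-empty names")
    landmarks <- lapply(landmarks, .as_polygon)
    for (nm_i in names(landmarks)) {
      p <- landmarks[[nm_i]]
      d <- sqrt((p[, 1] - tank_center[1])^2 + (p[, 2] - tank_center[2])^2)
      if (any(d > tank_radius))
        stop(sprintf("landmark '%s' extends outside the tank circle", nm_i))
    }
  }
  if (!is.null(home)) home <- .as_polygon(home)
  structure(list(tank_center = as.numeric(tank_center),
                 tank_radius = tank_radius,
                 landmarks = landmarks, home = home,
                 pixel_scale = pixel_scale,
                 video_size = as.numeric(video_size)),
            class = "arena_layout")
}

.as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2 || nrow(p) < 3) stop("a polygon needs an n x 2 matrix, n >= 3")
  storage.mode(p) <- "double"
  p
}

#' @export
print.arena_layout <- function(x, ...) {
  cat(sprintf("arena_layout: circular tank r = %g cm at (%g, %g) cm\n",
              x$tank_radius, x$tank_center[1], x$tank_center[2]))
  cat(sprintf("  %d landmark(s)%s; %g cm/px, %g x %g px video\n",
              length(x$landmarks),
              if (is.null(x$home)) "" else " + home",
              x$pixel_scale, x$video_size[1], x$video_size[2]))
  invisible(x)
}

#' Default synthetic arena
#'
#' A 1.5 m tank centred in a 1600 x 1200 px frame at 0.125 cm/px (so the tank
#' just spans the frame height), with a square home against the wall and two
#' free-standing landmarks, mimicking typical layouts used in tank
#' experiments with *Gymnotus*.
#'
#' @return An `arena_layout`.
#' @export
default_arena <- function() {
  home <- cbind(c(32, 52, 52, 32), c(65, 65, 85, 85))
  tri <- cbind(c(140, 152, 146), c(95, 95, 107))
  ngon <- function(cx, cy, r, n = 8) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  arena_layout(tank_center = c(100, 75), tank_radius = 75,
               landmarks = list(triangle = tri, cylinder = ngon(100, 35, 6)),
               home = home, pixel_scale = 0.125, video_size = c(1600, 1200))
}

# points-in-polygon, vectorized over points
.in_poly <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# distance from points to a polygon boundary; 0 for interior points
.dist_poly <- function(x, y, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(x))
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[if (k == n) 1L else k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2))
    d2 <- pmin(d2, (x - (a[1] + t * ab[1]))^2 + (y - (a[2] + t * ab[2]))^2)
  }
  d <- sqrt(d2)
  d[.in_poly(x, y, poly)] <- 0
  d
}

#' Distance from points to the nearest landmark
#'
#' Minimum distance from each point to the boundary of any landmark polygon
#' (including the home, if present); points inside a polygon have distance 0.
#'
#' @param arena an [arena_layout()].
#' @param x,y point coordinates (cm), vectorized.
#' @param include_home include the home polygon (default TRUE).
#' @return numeric vector of distances (cm); `Inf` if the arena has no
#'   landmarks.
#' @export
landmark_distance <- function(arena, x, y, include_home = TRUE) {
  polys <- arena$landmarks
  if (include_home && !is.null(arena$home)) polys <- c(polys, list(arena$home))
  if (!length(polys)) return(rep(Inf, length(x)))
  d <- rep(Inf, length(x))
  for (p in polys) d <- pmin(d, .dist_poly(x, y, p))
  d
}

# TRUE for points inside any solid (non-home) landmark
.in_solid_landmark <- function(arena, x, y) {
  inside <- rep(FALSE, length(x))
  for (p in arena$landmarks) inside <- inside | .in_poly(x, y, p)
  inside
}
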