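# Local planar geometry: equirectangular projection, bearings, path lengths,
# point-to-polyline distances. Trial extents are a few km, so planar
# approximations are well below the GPS noise floor (+-4.2 m).

EARTH_RADIUS_M <- 6371000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalise angles in degrees to [0, 360)
#' @param x angles in degrees.
#' @return angles wrapped to `[0, 360)`.
#' @export
wrap360 <- function(x) ((x %% 360) + 360) %% 360

#' Signed circular difference a - b in (-180, 180]
#' @param a,b angles in degrees.
#' @return signed difference in degrees.
#' @export
circ_diff <- function(a, b) {
  d <- wrap360(a - b)
  ifelse(d > 180, d - 360, d)
}

#' Local planar reference frame
#'
#' Defines an equirectangular projection centred on a reference point:
#' `x = R * dlon * cos(ref_lat)`, `y = R * dlat` (angles in radians,
#' R = 6371000 m). Exactly invertible, adequate for single-site extents.
#'
#' @param ref_lat,ref_lon reference point, degrees WGS84.
#' @return an object of class `local_frame`.
#' @export
local_frame <- function(ref_lat, ref_lon) {
  stopifnot(is.finite(ref_lat), is.finite(ref_lon),
            abs(ref_lat) <= 90, abs(ref_lon) <= 180)
  structure(list(ref_lat = ref_lat, ref_lon = ref_lon,
                 earth_radius = EARTH_RADIUS_M),
            class = "local_frame")
}

#' Project geographic coordinates into a local frame
#'
#' @param lat,lon vectors of degrees WGS84.
#' @param frame a [local_frame()].
#' @param max_km distance guard; points farther than this from the reference
#'   indicate frame misuse.
#' @return list with numeric vectors `x`, `y` (metres east/north of the
#'   reference).
#' @export
project_point <- function(lat, lon, frame, max_km = 50) {
  x <- frame$earth_radius * deg2rad(lon - frame$ref_lon) * cos(deg2rad(frame$ref_lat))
  y <- frame$earth_radius * deg2rad(lat - frame$ref_lat)
  if (any(sqrt(x^2 + y^2) > max_km * 1000)) {
    stop("point(s) beyond ", max_km, " km of the frame reference; wrong frame?")
  }
  list(x = x, y = y)
}

#' Invert the local projection back to degrees
#' @param x,y metres east/north of the frame reference.
#' @inheritParams project_point
#' @return list with vectors `lat`, `lon` in degrees.
#' @export
unproject_point <- function(x, y, frame) {
  lat <- frame$ref_lat + rad2deg(y / frame$earth_radius)
  lon <- frame$ref_lon + rad2deg(x / (frame$earth_radius * cos(deg2rad(frame$ref_lat))))
  list(lat = lat, lon = lon)
}

#' Project a track into a local frame
#'
#' @param track a `track` object (see [read_gpx()]).
#' @param frame a [local_frame()].
#' @return data.frame with columns `x`, `y`, `time`.
#' @export
project_track <- function(track, frame) {
  p <- project_point(track$points$lat, track$points$lon, frame)
  data.frame(x = p$x, y = p$y, time = track$points$time)
}

#' True bearing of the vector a -> b
#'
#' Clockwise angle from geographic north, in degrees `[0, 360)`. Vectorised.
#'
#' @param x1,y1 coordinates of a (metres in a local frame).
#' @param x2,y2 coordinates of b.
#' @return bearings in degrees.
#' @export
true_bearing <- function(x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  if (any(dx == 0 & dy == 0)) stop("undefined bearing: coincident points")
  wrap360(rad2deg(atan2(dx, dy)))
}

#' Convert a true bearing to a magnetic bearing
#'
#' @param true_deg true bearing, degrees.
#' @param declination magnetic declination, degrees, east positive.
#' @return magnetic bearing in `[0, 360)`.
#' @export
magnetic_bearing <- function(true_deg, declination) {
  stopifnot(all(is.finite(true_deg)), all(is.finite(declination)))
  wrap360(true_deg - declination)
}

#' Step lengths and cumulative path length of a planar point sequence
#' @param x,y coordinate vectors.
#' @return numeric vector `cum` of length `length(x)`: cumulative path length
#'   with `cum[1] = 0`.
#' @export
cum_path_length <- function(x, y) {
  n <- length(x)
  if (n < 1) stop("empty point sequence")
  c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
}

#' Path length between two indices of a planar point sequence
#'
#' Sum of consecutive Euclidean step lengths from index `i` to `j`.
#'
#' @param x,y coordinate vectors.
#' @param i,j indices with `1 <= i < j <= length(x)`.
#' @return metres.
#' @export
path_length <- function(x, y, i = 1L, j = length(x)) {
  n <- length(x)
  if (!(i >= 1 && j <= n && i < j)) stop("bad indices: need 1 <= i < j <= n")
  cum <- cum_path_length(x, y)
  cum[j] - cum[i]
}

#' Minimum distance from points to a polyline
#'
#' Perpendicular foot distance where the foot falls inside a segment,
#' otherwise distance to the nearest segment endpoint; minimised over all
#' segments. Vectorised over the query points.
#'
#' @param px,py query point coordinates.
#' @param lx,ly polyline vertex coordinates (>= 2 vertices).
#' @return numeric vector of distances in metres, one per query point.
#' @export
min_dist_to_polyline <- function(px, py, lx, ly) {
  m <- length(lx)
  if (m < 2) stop("degenerate polyline: need at least 2 vertices")
  np <- length(px)
  ax <- lx[-m]; ay <- ly[-m]
  vx <- lx[-1] - ax; vy <- ly[-1] - ay
  vv <- vx^2 + vy^2
  vv0 <- vv == 0
  vv[vv0] <- 1   # zero-length segments reduce to their start vertex
  if (as.double(np) * (m - 1) <= 4e6) {
    # fully vectorised: (segments x points) matrices, vectors recycle down
    # columns
    wx <- -outer(ax, px, "-")
    wy <- -outer(ay, py, "-")
    t <- (wx * vx + wy * vy) / vv
    t[t < 0 | vv0] <- 0
    t[t > 1] <- 1
    dx <- wx - t * vx
    dy <- wy - t * vy
    d2 <- dx^2 + dy^2
    return(sqrt(.colMins(d2, m - 1L, np)))
  }
  best <- rep(Inf, np)
  for (k in seq_len(m - 1L)) {
    wx <- px - ax[k]; wy <- py - ay[k]
    t <- if (vv0[k]) 0 else pmin(1, pmax(0, (wx * vx[k] + wy * vy[k]) / vv[k]))
    d2 <- (wx - t * vx[k])^2 + (wy - t * vy[k])^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# column minima of a matrix given as (n x p); matrixStats-style helper
.colMins <- function(x, n, p) {
  dim(x) <- c(n, p)
  apply(x, 2L, min)
}
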