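# Planar geometry helpers. All hex-grid work happens in a local azimuthal
# equal-area projection (meters) centered on the study region, so that
# "uniform hexagons" are uniform in ground distance rather than in degrees.

# mean Earth radius used by the local projection, meters
.EARTH_RADIUS <- 6371008.8

#' Project lon/lat to local planar coordinates
#'
#' Lambert azimuthal equal-area projection on a spherical Earth, centered on
#' `center`. Adequate for study regions tens of kilometres across; distortion
#' at 50 km from the center is well below one part in a thousand.
#'
#' @param lonlat two-column matrix (or length-2 vector) of lon/lat in decimal
#'   degrees, WGS84.
#' @param center length-2 numeric, lon/lat of the projection center.
#' @return two-column matrix of x/y in meters.
#' @export
project_planar <- function(lonlat, center) {
  if (is.null(dim(lonlat))) lonlat <- matrix(lonlat, ncol = 2)
  lon <- lonlat[, 1] * pi / 180
  lat <- lonlat[, 2] * pi / 180
  lon0 <- center[1] * pi / 180
  lat0 <- center[2] * pi / 180
  dlon <- lon - lon0
  denom <- 1 + sin(lat0) * sin(lat) + cos(lat0) * cos(lat) * cos(dlon)
  k <- sqrt(2 / denom)
  x <- .EARTH_RADIUS * k * cos(lat) * sin(dlon)
  y <- .EARTH_RADIUS * k * (cos(lat0) * sin(lat) - sin(lat0) * cos(lat) * cos(dlon))
  cbind(x = x, y = y)
}

#' Inverse of [project_planar()]
#'
#' @param xy two-column matrix of planar x/y in meters.
#' @param center length-2 numeric, lon/lat of the projection center.
#' @return two-column matrix of lon/lat in decimal degrees.
#' @export
unproject_planar <- function(xy, center) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  lon0 <- center[1] * pi / 180
  lat0 <- center[2] * pi / 180
  x <- xy[, 1]
  y <- xy[, 2]
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * .EARTH_RADIUS)))
  lat <- ifelse(rho == 0, lat0,
                asin(cos(c_ang) * sin(lat0) + y * sin(c_ang) * cos(lat0) / rho))
  lon <- ifelse(rho == 0, lon0,
                lon0 + atan2(x * sin(c_ang),
                             rho * cos(lat0) * cos(c_ang) - y * sin(lat0) * sin(c_ang)))
  cbind(lon = lon * 180 / pi, lat = lat * 180 / pi)
}

# Shoelace area of a closed or open ring (two-column matrix). Positive for
# counter-clockwise winding; callers wanting unsigned area take abs().
polygon_area <- function(ring) {
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Points-in-polygon test; ring is an open or closed two-column matrix.
points_in_polygon <- function(ring, pts) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  mgcv::in.out(as.matrix(ring), as.matrix(pts))
}

# TRUE when the ring is a simple polygon: no two non-adjacent edges intersect.
# O(n^2) segment test; boundary rings here are small (tens of vertices).
polygon_is_simple <- function(ring) {
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  seg <- function(i) rbind(ring[i, ], ring[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (shared vertex), incl. the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

# proper or improper intersection of two segments given as 2x2 matrices
segments_cross <- function(s1, s2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  p1 <- s1[1, ]; q1 <- s1[2, ]; p2 <- s2[1, ]; q2 <- s2[2, ]
  o1 <- orient(p1, q1, p2); o2 <- orient(p1, q1, q2)
  o3 <- orient(p2, q2, p1); o4 <- orient(p2, q2, q1)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, q1, p2)) || (o2 == 0 && on_seg(p1, q1, q2)) ||
    (o3 == 0 && on_seg(p2, q2, p1)) || (o4 == 0 && on_seg(p2, q2, q1))
}
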