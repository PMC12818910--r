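# Polygon / polyline helpers shared across modules.
# Coordinates are (x = column, y = row), 0-based, origin at the top-left
# pixel center. Signed area > 0 is the package's CCW convention.

#' Signed polygon area (shoelace)
#' @param pts n x 2 matrix of (x, y) vertices, closure implied.
#' @return signed area; positive for the package's CCW orientation.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Cumulative arc length of a polyline
#' @param pts n x 2 matrix.
#' @return numeric vector of length n starting at 0.
#' @export
arc_length <- function(pts) {
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(d))
}

# Resample an open polyline at given arc-length positions (linear).
resample_at <- function(pts, s_new) {
  s <- arc_length(pts)
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; pts <- pts[keep, , drop = FALSE]
  cbind(approx(s, pts[, 1], xout = s_new, rule = 2)$y,
        approx(s, pts[, 2], xout = s_new, rule = 2)$y)
}

# Uniformly resample a closed polygon (first vertex not repeated) to
# roughly `spacing` between consecutive points.
resample_closed <- function(pts, spacing = 1) {
  closed <- rbind(pts, pts[1, ])
  s <- arc_length(closed)
  total <- s[length(s)]
  n <- max(16L, round(total / spacing))
  s_new <- seq(0, total, length.out = n + 1)[-(n + 1)]
  resample_at(closed, s_new)
}

# First intersection of the ray origin + t*dir (t > 0) with a closed
# polygon; returns list(point, t) or NULL.
ray_polygon_intersection <- function(origin, dir, poly, t_max = Inf) {
  p1 <- poly
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  # solve origin + t*dir = p1 + w*(p2-p1), 0 <= w <= 1, t > 0
  den <- dir[1] * (-ey) - dir[2] * (-ex)
  rx <- p1[, 1] - origin[1]; ry <- p1[, 2] - origin[2]
  t <- (rx * (-ey) - ry * (-ex)) / den
  w <- (dir[1] * ry - dir[2] * rx) / den
  ok <- is.finite(t) & t > 1e-9 & w >= -1e-9 & w <= 1 + 1e-9 & t <= t_max
  if (!any(ok)) return(NULL)
  t_hit <- min(t[ok])
  list(point = origin + t_hit * dir, t = t_hit)
}

# Any self-intersection among non-adjacent edges of a closed polygon?
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  p1 <- pts
  p2 <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]  # edge n is adjacent to edge 1
    dxi <- p2[i, 1] - p1[i, 1]; dyi <- p2[i, 2] - p1[i, 2]
    dxj <- p2[j, 1] - p1[j, 1]; dyj <- p2[j, 2] - p1[j, 2]
    d1 <- cross2(dxi, dyi, p1[j, 1] - p1[i, 1], p1[j, 2] - p1[i, 2])
    d2 <- cross2(dxi, dyi, p2[j, 1] - p1[i, 1], p2[j, 2] - p1[i, 2])
    d3 <- cross2(dxj, dyj, p1[i, 1] - p1[j, 1], p1[i, 2] - p1[j, 2])
    d4 <- cross2(dxj, dyj, p2[i, 1] - p1[j, 1], p2[i, 2] - p1[j, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

# Rotate points about a center (standard rotation matrix in image coords).
rotate_points <- function(pts, theta_deg, center) {
  th <- theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  x <- pts[, 1] - center[1]; y <- pts[, 2] - center[2]
  cbind(ct * x - st * y + center[1], st * x + ct * y + center[2])
}
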