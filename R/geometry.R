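# Planar geometry primitives shared across the package. All coordinates are
# planar metres (projected CRS); rings are n x 2 matrices, open (first row not
# repeated). Everything here is internal.

# Signed area of a ring (shoelace). Positive for counter-clockwise rings.
geom_ring_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  sum(x * y2 - x2 * y) / 2
}

# Area-weighted centroid; falls back to the vertex mean for degenerate rings.
geom_centroid <- function(xy) {
  n <- nrow(xy)
  a <- geom_ring_area(xy)
  if (abs(a) < 1e-12) return(colMeans(xy))
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  cr <- x * y2 - x2 * y
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Even-odd ray casting, vectorised over query points. Points exactly on the
# boundary are classified by the crossing parity; the callers only use this on
# sample points that are almost surely off the boundary.
geom_point_in_ring <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from points (px, py) to segment (ax, ay)-(bx, by); also returns the
# clamped projection parameter t in [0, 1] and the foot of the perpendicular.
geom_point_seg <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  fx <- ax + t * dx; fy <- ay + t * dy
  list(dist = sqrt((px - fx)^2 + (py - fy)^2), t = t, x = fx, y = fy)
}

# TRUE when open segments p1-p2 and p3-p4 properly cross (shared endpoints do
# not count). Used for ring-validity checks.
geom_segs_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

# A ring is simple when no two non-adjacent edges cross and its area is nonzero.
geom_ring_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3 || abs(geom_ring_area(xy)) < 1e-12) return(FALSE)
  seg <- function(i) list(xy[i, ], xy[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex), including the wrap-around pair
      if (j == i + 1 || (i == 1 && j == n)) next
      a <- seg(i); b <- seg(j)
      if (geom_segs_cross(a[[1]], a[[2]], b[[1]], b[[2]])) return(FALSE)
    }
  }
  TRUE
}

geom_bbox <- function(xy) {
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]),
    xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# Length of a polyline given as an n x 2 matrix.
geom_polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# Point at arc-length s along a polyline (clamped to its ends).
geom_polyline_interpolate <- function(xy, s) {
  seg_len <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  s <- pmin(max(cum), pmax(0, s))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(seg_len))
  f <- ifelse(seg_len[i] > 0, (s - cum[i]) / seg_len[i], 0)
  cbind(xy[i, 1] + f * (xy[i + 1, 1] - xy[i, 1]),
        xy[i, 2] + f * (xy[i + 1, 2] - xy[i, 2]))
}
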