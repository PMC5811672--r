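# 2D polygon primitives in image pixel space (origin top-left, y down).
# Polygons are ordered vertex matrices, implicitly closed, winding-agnostic.

EPS <- 1e-9

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

# Strict orientation sign of (p1->p2, p1->p3).
orient <- function(x1, y1, x2, y2, x3, y3) {
  (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
}

segments_properly_intersect <- function(a1, a2, b1, b2) {
  d1 <- orient(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- orient(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- orient(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- orient(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  ((d1 > EPS && d2 < -EPS) || (d1 < -EPS && d2 > EPS)) &&
    ((d3 > EPS && d4 < -EPS) || (d3 < -EPS && d4 > EPS))
}

# Simplicity: no two non-adjacent edges intersect, and no adjacent edges
# overlap by spiking back. O(n^2); ROI polygons are small.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  idx <- function(i) ((i - 1L) %% n) + 1L
  seg <- function(i) list(poly[idx(i), ], poly[idx(i + 1L), ])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      si <- seg(i); sj <- seg(j)
      if (segments_properly_intersect(si[[1]], si[[2]], sj[[1]], sj[[2]])) return(FALSE)
    }
  }
  TRUE
}

# Vectorized strict-interior containment via the winding number, with an
# explicit on-boundary test (boundary counts as outside: a circle drawn on a
# compartment border would straddle compartments visually).
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  wn <- integer(length(px))
  on_edge <- logical(length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    side <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    scale <- max(abs(c(x1, y1, x2, y2, 1)))
    on_seg <- abs(side) <= EPS * scale * scale &
      px >= pmin(x1, x2) - EPS & px <= pmax(x1, x2) + EPS &
      py >= pmin(y1, y2) - EPS & py <= pmax(y1, y2) + EPS
    on_edge <- on_edge | on_seg
    up <- y1 <= py & y2 > py & side > 0
    down <- y1 > py & y2 <= py & side < 0
    wn <- wn + up - down
  }
  wn != 0L & !on_edge
}
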