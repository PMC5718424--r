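# Planar geometry primitives. All coordinates are in a projected, metre-unit
# CRS; nothing here reprojects. Polygons are 2-column matrices of ring
# vertices (not repeated at the end); a polygon-with-holes is a list of rings
# with the first ring the outer boundary; a multipolygon is a list of such
# lists.

#' Signed shoelace area of a ring
#'
#' @param ring two-column numeric matrix of vertices (open ring: the first
#'   vertex is not repeated at the end).
#' @return signed area in squared coordinate units (positive for
#'   counter-clockwise rings).
#' @keywords internal
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Point-in-ring test by ray casting
#'
#' Even-odd rule; points exactly on an edge are treated as inside.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param ring two-column vertex matrix.
#' @return logical vector.
#' @keywords internal
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test points against a (multi)polygon with holes
#' @keywords internal
point_in_polygon <- function(px, py, polygon) {
  polys <- normalize_multipolygon(polygon)
  inside <- rep(FALSE, length(px))
  for (rings in polys) {
    this <- point_in_ring(px, py, rings[[1L]])
    if (length(rings) > 1L) {
      for (h in rings[-1L]) this <- this & !point_in_ring(px, py, h)
    }
    inside <- inside | this
  }
  inside
}

#' Clip a ring against a convex window (Sutherland-Hodgman)
#'
#' @param ring subject ring (two-column matrix, any simple polygon).
#' @param window convex clip ring, counter-clockwise.
#' @return clipped ring matrix, possibly with zero rows.
#' @keywords internal
clip_ring_convex <- function(ring, window) {
  out <- ring
  nw <- nrow(window)
  for (k in seq_len(nw)) {
    if (nrow(out) == 0L) break
    a <- window[k, ]
    b <- window[if (k == nw) 1L else k + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    # side > 0 <=> point is to the left of edge a->b (inside for CCW window)
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    n <- nrow(out)
    prev <- c(n, seq_len(n - 1L))
    res_x <- numeric(0); res_y <- numeric(0)
    for (i in seq_len(n)) {
      p <- prev[i]
      cur_in <- side[i] >= 0
      prev_in <- side[p] >= 0
      if (cur_in != prev_in) {
        t <- side[p] / (side[p] - side[i])
        res_x <- c(res_x, out[p, 1] + t * (out[i, 1] - out[p, 1]))
        res_y <- c(res_y, out[p, 2] + t * (out[i, 2] - out[p, 2]))
      }
      if (cur_in) {
        res_x <- c(res_x, out[i, 1])
        res_y <- c(res_y, out[i, 2])
      }
    }
    out <- cbind(res_x, res_y)
  }
  out
}

#' Area of the intersection of a (multi)polygon with a convex window
#'
#' Holes are subtracted. Used for hexagon-cell/boundary overlap tests and the
#' area-conservation invariant.
#' @keywords internal
clip_area_convex <- function(polygon, window) {
  polys <- normalize_multipolygon(polygon)
  total <- 0
  for (rings in polys) {
    outer <- clip_ring_convex(rings[[1L]], window)
    if (nrow(outer) >= 3L) total <- total + abs(ring_area_signed(outer))
    if (length(rings) > 1L) {
      for (h in rings[-1L]) {
        hc <- clip_ring_convex(h, window)
        if (nrow(hc) >= 3L) total <- total - abs(ring_area_signed(hc))
      }
    }
  }
  total
}

# Accept a bare ring, a list of rings, or a list of lists of rings, and
# return the multipolygon form (list of list-of-rings).
#' @keywords internal
normalize_multipolygon <- function(polygon) {
  if (is.matrix(polygon)) return(list(list(polygon)))
  stopifnot(is.list(polygon), length(polygon) > 0L)
  if (is.matrix(polygon[[1L]])) return(list(polygon))
  polygon
}

#' Total area of a (multi)polygon, holes subtracted
#' @keywords internal
polygon_area <- function(polygon) {
  polys <- normalize_multipolygon(polygon)
  total <- 0
  for (rings in polys) {
    total <- total + abs(ring_area_signed(rings[[1L]]))
    if (length(rings) > 1L) {
      for (h in rings[-1L]) total <- total - abs(ring_area_signed(h))
    }
  }
  total
}

# Proper-crossing test between segments p1-p2 and q1-q2 (shared endpoints
# between adjacent ring edges are not crossings).
#' @keywords internal
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Check a ring for self-intersection
#'
#' O(n^2) pairwise test over non-adjacent edges; adequate for digitized
#' waterbody outlines.
#' @keywords internal
ring_is_simple <- function(ring) {
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent edges (they share a vertex)
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      if (segments_cross(ring[i, ], ring[nxt[i], ], ring[j, ], ring[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

#' Bounding box of a (multi)polygon
#' @keywords internal
polygon_bbox <- function(polygon) {
  polys <- normalize_multipolygon(polygon)
  xs <- unlist(lapply(polys, function(rings) lapply(rings, function(r) r[, 1])))
  ys <- unlist(lapply(polys, function(rings) lapply(rings, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Centroid of the outer ring of a polygon
#' @keywords internal
ring_centroid <- function(ring) {
  a <- ring_area_signed(ring)
  if (abs(a) < .Machine$double.eps) return(colMeans(ring))
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  cross <- x[j] * y - x * y[j]
  c(sum((x[j] + x) * cross), sum((y[j] + y) * cross)) / (6 * a)
}
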