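# Planar geometry primitives on lon/lat polygons.
#
# Polygons are two-column numeric matrices (lon, lat), one ring, not
# necessarily closed (the closing edge is implied). All tests are done in
# plain lon/lat degrees; at Mediterranean latitudes this is adequate for the
# membership and overlap decisions the pipeline makes (no distances or true
# areas are ever reported).

#' Signed area of a polygon ring (shoelace formula)
#'
#' @param ring two-column matrix of (lon, lat) vertices
#' @return signed area in squared degrees; positive for counter-clockwise
#' @keywords internal
ring_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' Points exactly on an edge may fall on either side; callers that need a
#' deterministic border rule (EEZ assignment) resolve ties themselves.
#'
#' @param px,py point coordinates
#' @param ring two-column (lon, lat) matrix
#' @return logical
#' @keywords internal
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Clip a ring against one half-plane keep(p) with edge intersection inter(a, b).
clip_halfplane <- function(ring, keep, inter) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- matrix(numeric(0), ncol = 2)
  prev <- ring[n, ]
  prev_in <- keep(prev)
  for (i in seq_len(n)) {
    cur <- ring[i, ]
    cur_in <- keep(cur)
    if (cur_in) {
      if (!prev_in) out <- rbind(out, inter(prev, cur))
      out <- rbind(out, cur)
    } else if (prev_in) {
      out <- rbind(out, inter(prev, cur))
    }
    prev <- cur
    prev_in <- cur_in
  }
  out
}

#' Clip a polygon ring to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param ring two-column (lon, lat) matrix, convex or concave, single ring
#' @param xmin,xmax,ymin,ymax rectangle bounds
#' @return the clipped ring (possibly with zero rows)
#' @keywords internal
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  lerp <- function(a, b, t) a + t * (b - a)
  ix <- function(bound, axis) {
    function(a, b) {
      t <- (bound - a[axis]) / (b[axis] - a[axis])
      c(lerp(a[1], b[1], t), lerp(a[2], b[2], t))
    }
  }
  ring <- clip_halfplane(ring, function(p) p[1] >= xmin, ix(xmin, 1))
  ring <- clip_halfplane(ring, function(p) p[1] <= xmax, ix(xmax, 1))
  ring <- clip_halfplane(ring, function(p) p[2] >= ymin, ix(ymin, 2))
  ring <- clip_halfplane(ring, function(p) p[2] <= ymax, ix(ymax, 2))
  ring
}

#' Area of overlap between a rectangle and a polygon ring
#'
#' @inheritParams clip_ring_rect
#' @return non-negative overlap area in squared degrees
#' @keywords internal
rect_ring_overlap <- function(ring, xmin, xmax, ymin, ymax) {
  abs(ring_area(clip_ring_rect(ring, xmin, xmax, ymin, ymax)))
}

#' Repair a polygon ring
#'
#' Drops duplicated consecutive vertices and an explicit closing vertex;
#' degenerate rings (fewer than 3 distinct vertices or zero area) are
#' rejected. Self-intersecting rings are not untangled: the even-odd
#' point test and the clipper both behave consistently on them, which is
#' all the pipeline's membership decisions require.
#'
#' @param ring two-column matrix
#' @return cleaned ring
#' @keywords internal
repair_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2) stop_mesa("polygon ring must have two columns (lon, lat)")
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ])) {
    ring <- ring[-nrow(ring), , drop = FALSE]
  }
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) < 3 || abs(ring_area(ring)) == 0) {
    stop_mesa("degenerate polygon ring (fewer than 3 distinct vertices or zero area)")
  }
  ring
}
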