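# Internal 2D computational-geometry helpers used by the mesh and growth
# modules. All polygons are plain two-column matrices of vertex coordinates,
# open (last vertex != first); orientation conventions are handled by callers.

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counterclockwise vertex order.
#'
#' @param poly two-column matrix of vertices (open ring).
#' @return signed area.
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Triangle areas for a mesh (vectorized shoelace)
#' @keywords internal
triangle_areas <- function(pos, tri) {
  a <- pos[tri[, 1], , drop = FALSE]
  b <- pos[tri[, 2], , drop = FALSE]
  cc <- pos[tri[, 3], , drop = FALSE]
  abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
        (cc[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
}

#' Point-in-polygon test (ray casting, boundary counts as inside)
#'
#' @param px,py coordinates of query points (vectors).
#' @param poly two-column matrix of polygon vertices (open ring).
#' @param edge_tol absolute distance below which a point is treated as lying
#'   on an edge (and therefore inside).
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly, edge_tol = 0) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  for (q in seq_along(px)) {
    x <- px[q]; y <- py[q]
    # on-edge check
    if (edge_tol >= 0) {
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx * dx + dy * dy
      tpar <- ((x - x1) * dx + (y - y1) * dy) / pmax(L2, .Machine$double.xmin)
      tpar <- pmin(pmax(tpar, 0), 1)
      d2 <- (x1 + tpar * dx - x)^2 + (y1 + tpar * dy - y)^2
      if (any(d2 <= edge_tol^2)) { inside[q] <- TRUE; next }
    }
    # crossing number
    cross <- (y1 > y) != (y2 > y)
    if (any(cross)) {
      xin <- x1[cross] + (y - y1[cross]) / (y2[cross] - y1[cross]) *
        (x2[cross] - x1[cross])
      inside[q] <- (sum(xin > x) %% 2) == 1
    }
  }
  inside
}

#' Proper intersection test for two segments
#'
#' Shared endpoints do not count as an intersection; collinear overlap does.
#' @keywords internal
segments_intersect <- function(p1, p2, q1, q2, tol = 0) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) <= tol) 0 else sign(v)
  }
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
    return(TRUE)
  FALSE
}

#' Vectorized test: does segment (a, b) cross any polygon edge?
#'
#' Edges sharing an endpoint with the segment (within tol) are skipped.
#' @keywords internal
segment_crosses_boundary <- function(a, b, poly, tol) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  # skip edges with an endpoint coincident with a or b
  shared <- (abs(x1 - a[1]) < tol & abs(y1 - a[2]) < tol) |
    (abs(x2 - a[1]) < tol & abs(y2 - a[2]) < tol) |
    (abs(x1 - b[1]) < tol & abs(y1 - b[2]) < tol) |
    (abs(x2 - b[1]) < tol & abs(y2 - b[2]) < tol)
  d <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  o1 <- d(a[1], a[2], b[1], b[2], x1, y1)
  o2 <- d(a[1], a[2], b[1], b[2], x2, y2)
  o3 <- d(x1, y1, x2, y2, a[1], a[2])
  o4 <- d(x1, y1, x2, y2, b[1], b[2])
  hit <- (sign(o1) != sign(o2)) & (sign(o3) != sign(o4)) &
    o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0 & !shared
  any(hit)
}

#' Is a polygon simple (no self-intersection)?
#'
#' Quadratic-time check used only at diagnostic strides.
#' @keywords internal
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(TRUE)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  d <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):(if (i == 1) n - 1 else n)
    o1 <- d(x1[i], y1[i], x2[i], y2[i], x1[js], y1[js])
    o2 <- d(x1[i], y1[i], x2[i], y2[i], x2[js], y2[js])
    o3 <- d(x1[js], y1[js], x2[js], y2[js], x1[i], y1[i])
    o4 <- d(x1[js], y1[js], x2[js], y2[js], x2[i], y2[i])
    hit <- (sign(o1) != sign(o2)) & (sign(o3) != sign(o4)) &
      o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0
    if (any(hit)) return(FALSE)
  }
  TRUE
}
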