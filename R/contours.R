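#' Closed planar contour
#'
#' Constructs a closed, counterclockwise-oriented polygonal contour from a
#' two-column matrix of vertex coordinates in millimetres. Contours are the
#' geometric atom of the package: lumen and internal elastic lamina (IEL)
#' boundaries and plaque-region outlines are all contours.
#'
#' The vertex list is interpreted as a closed polygon (the last vertex connects
#' back to the first; a duplicated closing vertex is dropped). Orientation is
#' normalized to counterclockwise.
#'
#' @param points numeric matrix (or data.frame) with columns x, y in mm.
#' @param check if `TRUE` (default) validate invariants: at least 8 vertices,
#'   finite coordinates, simple (non-self-intersecting) polygon.
#' @return An object of class `"contour"`: a numeric matrix with columns
#'   `x`, `y`, counterclockwise, without a repeated closing vertex.
#' @export
contour <- function(points, check = TRUE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("contour points must have two columns (x, y)")
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n >= 2L && isTRUE(all(pts[1L, ] == pts[n, ]))) pts <- pts[-n, , drop = FALSE]
  if (check) {
    if (nrow(pts) < 8L) stop("contour needs at least 8 vertices, got ", nrow(pts))
    if (!all(is.finite(pts))) stop("contour coordinates must be finite")
  }
  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  if (check && !is_simple_polygon(pts)) stop("contour is self-intersecting")
  colnames(pts) <- c("x", "y")
  class(pts) <- c("contour", "matrix", "array")
  pts
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> %d vertices, area %.4f mm^2, centroid (%.3f, %.3f)\n",
              nrow(x), polygon_area(x), polygon_centroid(x)[1], polygon_centroid(x)[2]))
  invisible(x)
}

#' Signed polygon area (shoelace formula)
#'
#' @param pts two-column coordinate matrix (closed implicitly).
#' @return signed area in mm^2; positive for counterclockwise orientation.
#' @export
polygon_area <- function(pts) {
  pts <- unclass(as.matrix(pts))
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid
#' @param pts two-column coordinate matrix.
#' @return numeric length-2 (x, y) centroid of the enclosed region.
#' @export
polygon_centroid <- function(pts) {
  pts <- unclass(as.matrix(pts))
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(pts) {
  pts <- unclass(as.matrix(pts))
  d <- pts[c(seq_len(nrow(pts))[-1], 1L), , drop = FALSE] - pts
  sum(sqrt(rowSums(d^2)))
}

# Segment-intersection based simplicity test; O(n^2) with bbox prefilter.
is_simple_polygon <- function(pts) {
  pts <- unclass(as.matrix(pts))
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]           # skip edges adjacent to edge i
    if (!length(j)) next
    if (.segments_intersect_any(a[i, ], b[i, ], a[j, , drop = FALSE], b[j, , drop = FALSE]))
      return(FALSE)
  }
  TRUE
}

.segments_intersect_any <- function(p1, p2, q1, q2) {
  d1 <- .cross2(p2 - p1, t(q1) - p1)
  d2 <- .cross2(p2 - p1, t(q2) - p1)
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) - (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

.cross2 <- function(v, w) v[1] * w[2, ] - v[2] * w[1, ]

#' Resample a contour to uniform arc length
#'
#' Linear interpolation along the closed polyline at `n` equally spaced arc
#' positions, starting at the first vertex. Used before offsetting so the
#' vertex normal field is stable.
#'
#' @param c a [contour()].
#' @param n number of output vertices (default 128).
#' @return a [contour()] with `n` vertices.
#' @export
resample_contour <- function(c, n = 128L) {
  pts <- unclass(as.matrix(c))
  m <- nrow(pts)
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] - closed[-(m + 1L), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[m + 1L]
  target <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(s, closed[, 1], xout = target)$y
  y <- stats::approx(s, closed[, 2], xout = target)$y
  contour(cbind(x, y), check = FALSE)
}

#' Offset a contour along its outward normal field
#'
#' Moves every vertex a distance `t` along the outward vertex normal (the
#' normalized average of the two adjacent edge normals). The contour is first
#' resampled to uniform arc length so the normal field is well conditioned.
#' Used to build the media and adventitia bands from the IEL contour.
#'
#' @param c a [contour()].
#' @param t offset thickness in mm, non-negative.
#' @param direction `"outward"` (default) or `"inward"`.
#' @param n number of resampled vertices (default 128; pass `NULL` to keep the
#'   input vertices).
#' @return the offset [contour()].
#' @export
offset_contour <- function(c, t, direction = c("outward", "inward"), n = 128L) {
  direction <- match.arg(direction)
  if (!is.finite(t) || t < 0) stop("offset thickness must be non-negative")
  if (t == 0) return(if (is.null(n)) c else resample_contour(c, n))
  pts <- if (is.null(n)) unclass(as.matrix(c)) else unclass(as.matrix(resample_contour(c, n)))
  nv <- nrow(pts)
  nxt <- c(2:nv, 1L); prv <- c(nv, 1:(nv - 1L))
  e_next <- pts[nxt, , drop = FALSE] - pts
  e_prev <- pts - pts[prv, , drop = FALSE]
  # outward normal of a CCW polygon is the right-hand normal (ny, -nx)
  n1 <- cbind(e_prev[, 2], -e_prev[, 1])
  n2 <- cbind(e_next[, 2], -e_next[, 1])
  n1 <- n1 / sqrt(rowSums(n1^2)); n2 <- n2 / sqrt(rowSums(n2^2))
  nrm <- n1 + n2
  len <- sqrt(rowSums(nrm^2))
  if (any(len < 1e-9)) stop("degenerate normal while offsetting by t = ", t)
  nrm <- nrm / len
  sgn <- if (direction == "outward") 1 else -1
  out <- pts + sgn * t * nrm
  res <- try(contour(out, check = TRUE), silent = TRUE)
  if (inherits(res, "try-error"))
    stop("offset by t = ", format(t), " mm produced a self-intersecting contour")
  if (sgn * (polygon_area(res) - polygon_area(contour(pts, check = FALSE))) <= 0)
    stop("offset by t = ", format(t), " mm collapsed the contour")
  res
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray-casting test, vectorized over query points.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly two-column polygon matrix.
#' @return logical vector, `TRUE` for points inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- unclass(as.matrix(poly))
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
  inside <- logical(length(px))
  for (k in seq_len(n)) {
    crosses <- ((ys[k] > py) != (ye[k] > py))
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      idx <- which(crosses)[xint > px[crosses]]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

# Radial crossings of rays from `origin` at angles `theta` with polygon `poly`.
# Returns a list (one element per angle) of sorted crossing radii; for a
# star-shaped polygon enclosing the origin each list element has length 1
# if intervals = FALSE (max crossing taken), else all crossings.
ray_crossings <- function(theta, poly, origin = c(0, 0)) {
  poly <- unclass(as.matrix(poly))
  n <- nrow(poly)
  ax <- poly[, 1] - origin[1]; ay <- poly[, 2] - origin[2]
  bx <- ax[c(2:n, 1L)]; by <- ay[c(2:n, 1L)]
  out <- vector("list", length(theta))
  for (i in seq_along(theta)) {
    dx <- cos(theta[i]); dy <- sin(theta[i])
    # ray-frame coordinates: u along the ray, v across it; a crossing of the
    # half-line {v = 0, u > 0} is counted with the half-open sign rule so a
    # vertex exactly on the ray is counted once
    ua <- ax * dx + ay * dy; va <- ax * dy - ay * dx
    ub <- bx * dx + by * dy; vb <- bx * dy - by * dx
    cross <- (va > 0) != (vb > 0)
    if (any(cross)) {
      t <- va[cross] / (va[cross] - vb[cross])
      r <- ua[cross] + t * (ub[cross] - ua[cross])
      out[[i]] <- sort(r[r > 0])
    } else out[[i]] <- numeric(0)
  }
  out
}

# Radius of a star-shaped contour at given angles about `origin`
# (furthest positive crossing).
contour_radius_at <- function(c, theta, origin = c(0, 0)) {
  cr <- ray_crossings(theta, c, origin)
  vapply(cr, function(r) if (length(r)) max(r) else NA_real_, 0)
}

# Minimum distance from points (px, py) to a closed polyline.
dist_to_polyline <- function(px, py, poly) {
  poly <- unclass(as.matrix(poly))
  n <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- ax[c(2:n, 1L)]; by <- ay[c(2:n, 1L)]
  ex <- bx - ax; ey <- by - ay
  el2 <- pmax(ex^2 + ey^2, 1e-300)
  d2 <- rep(Inf, length(px))
  for (k in seq_len(n)) {
    t <- pmin(pmax(((px - ax[k]) * ex[k] + (py - ay[k]) * ey[k]) / el2[k], 0), 1)
    dk <- (px - (ax[k] + t * ex[k]))^2 + (py - (ay[k] + t * ey[k]))^2
    d2 <- pmin(d2, dk)
  }
  sqrt(d2)
}

# Minimum distance between two closed polylines (vertex-to-segment, both ways;
# exact for non-crossing polylines up to vertex density).
polyline_min_distance <- function(a, b) {
  a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  min(min(dist_to_polyline(a[, 1], a[, 2], b)),
      min(dist_to_polyline(b[, 1], b[, 2], a)))
}
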