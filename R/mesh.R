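#' Generate a multi-region finite-element mesh of a layered geometry
#'
#' Triangulates the annular wall domain between the lumen and the adventitia
#' outer boundary into linear (three-node) triangles that conform to every
#' material interface: lumen, region boundaries inside the intima, IEL,
#' media/adventitia interface and the outer boundary. The mesh is built on
#' radial node columns (the domain is star-shaped about the lumen centroid):
#' each column carries a node exactly on every interface crossed by its ray,
#' with graded filler nodes in between, and adjacent columns are stitched by a
#' monotone two-pointer strip triangulation, so the mesh is conforming by
#' construction.
#'
#' Element size grades from `h_superficial` at the lumen to `h_bulk` at the
#' outer boundary; near the lumen the leg spacing is `h_superficial / sqrt(2)`
#' so that the longest edge of every lumen-adjacent element stays below
#' `h_superficial` (default 45 um, below the 50 um superficial-layer
#' requirement).
#'
#' @param geom a [build_layered_geometry()] result.
#' @param h_superficial target element size (longest edge) at the lumen, mm;
#'   must be < 0.05.
#' @param h_bulk target element size at the outer boundary, mm.
#' @return object of class `"fe_mesh"`: `nodes` (N x 2, mm), `tri` (M x 3
#'   node indices, counterclockwise), `region` (character, per element),
#'   `lumen_loop` / `outer_loop` (ordered node-index cycles), `superficial`
#'   (element ids within 50 um of the lumen), `h` and area bookkeeping.
#' @export
generate_mesh <- function(geom, h_superficial = 0.045, h_bulk = 0.15) {
  if (!inherits(geom, "layered_geometry")) stop("geom must be a layered_geometry")
  if (h_superficial >= 0.05)
    stop("h_superficial must be below 0.05 mm (superficial layer definition)")
  if (h_bulk < h_superficial) stop("h_bulk must be >= h_superficial")

  leg_sup <- h_superficial / sqrt(2)
  per <- polygon_perimeter(geom$lumen)
  # chord factor < 1: the band within 50 um of the lumen spans two element
  # rows whose chord grows with radius, so the angular spacing is tightened
  n_theta <- max(48L, 2L * ceiling(per / (0.85 * leg_sup) / 2))
  # anchor the angular grid to the lumen contour's first vertex so that
  # rotating the input geometry rotates the mesh (and hence the solution)
  # exactly with it
  theta0 <- atan2(geom$lumen[1, 2], geom$lumen[1, 1])
  theta <- theta0 + seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  r_lum <- contour_radius_at(geom$lumen, theta)
  r_iel <- contour_radius_at(geom$iel, theta)
  r_med <- contour_radius_at(geom$media_outer, theta)
  r_adv <- contour_radius_at(geom$adventitia_outer, theta)
  if (anyNA(r_lum) || anyNA(r_iel) || anyNA(r_med) || anyNA(r_adv))
    stop("geometry is not star-shaped about the lumen centroid; cannot mesh")

  region_cross <- lapply(geom$regions, function(r)
    ray_crossings(theta, r$boundary))

  snap <- leg_sup / 2
  mean_wall <- mean(r_adv - r_lum)

  # graded subdivision count for a gap [ra, rb] of column j; when `force` is
  # given it overrides the count (used to share counts across columns so
  # neighbouring columns cannot flip across a rounding threshold)
  gap_nodes <- function(ra, rb, j, force = NA) {
    h_of <- function(r) {
      frac <- pmin(pmax((r - r_lum[j]) / mean_wall, 0), 1)
      leg_sup + (h_bulk - leg_sup) * frac
    }
    rg <- seq(ra, rb, length.out = 64L)
    dens <- 1 / h_of(rg)
    cum <- c(0, cumsum((dens[-1] + dens[-64L]) / 2 * diff(rg)))
    nsub <- if (!is.na(force)) force
            else if (ra - r_lum[j] < 0.08) max(1L, ceiling(cum[64L] - 0.05))
            else max(1L, round(cum[64L]))
    list(count = cum[64L],
         radii = if (nsub == 1L) ra else
           c(ra, stats::approx(cum, rg,
                               xout = cum[64L] * seq_len(nsub - 1L) / nsub)$y))
  }
  # shared counts for the media and adventitia layers
  n_media <- max(1L, round(mean(vapply(seq_len(n_theta), function(j)
    gap_nodes(r_iel[j], r_med[j], j)$count, 0))))
  n_adv <- max(1L, round(mean(vapply(seq_len(n_theta), function(j)
    gap_nodes(r_med[j], r_adv[j], j)$count, 0))))

  # Per-column radii between global interfaces, with region endpoints inserted
  # in the intima and graded filler nodes. Returns radii plus the indices of
  # the global interface nodes (lumen, iel, media, outer).
  build_column <- function(j) {
    levels <- c(r_lum[j], r_iel[j], r_med[j], r_adv[j])
    ins <- numeric(0)
    for (rc in region_cross) {
      rr <- rc[[j]]
      if (length(rr) %% 2L) rr <- rr[-length(rr)]
      rr <- rr[rr > r_lum[j] + 1e-9 & rr < r_iel[j] - 1e-9]
      ins <- c(ins, rr)
    }
    ins <- sort(unique(ins))
    if (length(ins)) {
      keep <- rep(TRUE, length(ins))
      ref <- c(levels, -Inf)
      last <- -Inf
      for (i in seq_along(ins)) {
        if (min(abs(ins[i] - levels)) < snap || ins[i] - last < snap)
          keep[i] <- FALSE
        else last <- ins[i]
      }
      ins <- ins[keep]
    }
    anchors <- sort(unique(c(levels, ins)))
    radii <- numeric(0)
    for (g in seq_len(length(anchors) - 1L)) {
      ra <- anchors[g]; rb <- anchors[g + 1L]
      force <- if (isTRUE(all.equal(c(ra, rb), c(r_iel[j], r_med[j])))) n_media
               else if (isTRUE(all.equal(c(ra, rb), c(r_med[j], r_adv[j])))) n_adv
               else NA
      radii <- c(radii, gap_nodes(ra, rb, j, force = force)$radii)
    }
    radii <- c(radii, anchors[length(anchors)])
    iface <- vapply(levels, function(lv) which.min(abs(radii - lv)), 1L)
    list(r = radii, iface = iface)
  }

  cols <- lapply(seq_len(n_theta), build_column)
  col_n <- vapply(cols, function(cc) length(cc$r), 1L)
  col_off <- cumsum(c(0L, col_n[-n_theta]))
  n_nodes <- sum(col_n)
  nodes <- matrix(0, n_nodes, 2L)
  for (j in seq_len(n_theta)) {
    idx <- col_off[j] + seq_len(col_n[j])
    nodes[idx, 1] <- cols[[j]]$r * cos(theta[j])
    nodes[idx, 2] <- cols[[j]]$r * sin(theta[j])
  }

  # stitch strips between adjacent columns, layer by layer
  tris <- vector("list", n_theta)
  for (j in seq_len(n_theta)) {
    jn <- if (j == n_theta) 1L else j + 1L
    L <- cols[[j]]; R <- cols[[jn]]
    tri_j <- matrix(0L, 0L, 3L)
    for (layer in 1:3) {
      li <- L$iface[layer]:L$iface[layer + 1L]
      ri <- R$iface[layer]:R$iface[layer + 1L]
      sl <- (L$r[li] - L$r[li[1]]) / max(L$r[li[length(li)]] - L$r[li[1]], 1e-12)
      sr <- (R$r[ri] - R$r[ri[1]]) / max(R$r[ri[length(ri)]] - R$r[ri[1]], 1e-12)
      gl <- col_off[j] + li
      gr <- col_off[jn] + ri
      i <- 1L; k <- 1L
      nl <- length(gl); nr <- length(gr)
      while (i < nl || k < nr) {
        adv_left <- if (i >= nl) FALSE
          else if (k >= nr) TRUE
          else if (abs(sl[i + 1L] - sr[k + 1L]) < 1e-9) ((i + k + j) %% 2L == 0L)
          else sl[i + 1L] < sr[k + 1L]
        if (adv_left) {
          tri_j <- rbind(tri_j, c(gl[i], gr[k], gl[i + 1L]))
          i <- i + 1L
        } else {
          tri_j <- rbind(tri_j, c(gl[i], gr[k], gr[k + 1L]))
          k <- k + 1L
        }
      }
    }
    tris[[j]] <- tri_j
  }
  tri <- do.call(rbind, tris)

  # enforce counterclockwise orientation
  ax <- nodes[tri[, 1], 1]; ay <- nodes[tri[, 1], 2]
  bx <- nodes[tri[, 2], 1]; by <- nodes[tri[, 2], 2]
  cx <- nodes[tri[, 3], 1]; cy <- nodes[tri[, 3], 2]
  a2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  flip <- a2 < 0
  if (any(flip)) { tmp <- tri[flip, 2L]; tri[flip, 2L] <- tri[flip, 3L]; tri[flip, 3L] <- tmp }
  a2 <- abs(a2)
  if (any(a2 <= 1e-14))
    stop("degenerate (zero-area) element produced; geometry has a sliver ",
         "thinner than the 5 um resolution floor")

  cxc <- (ax + bx + cx) / 3
  cyc <- (ay + by + cy) / 3
  region <- classify_points(geom, cxc, cyc)

  lumen_loop <- col_off + vapply(cols, function(cc) cc$iface[1], 1L)
  outer_loop <- col_off + vapply(cols, function(cc) cc$iface[4], 1L)

  mesh <- structure(list(nodes = nodes, tri = tri, region = region,
                         lumen_loop = as.integer(lumen_loop),
                         outer_loop = as.integer(outer_loop),
                         n_theta = n_theta,
                         h = c(superficial = h_superficial, bulk = h_bulk),
                         geom = geom),
                    class = "fe_mesh")
  mesh$superficial <- extract_superficial_set(mesh, depth_um = 50)
  mesh
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d nodes, %d triangles (%s), %d superficial\n",
              nrow(x$nodes), nrow(x$tri),
              paste(sprintf("%s: %d", names(table(x$region)), table(x$region)),
                    collapse = ", "),
              length(x$superficial)))
  invisible(x)
}

#' Element ids of the superficial band
#'
#' Elements whose reference-configuration centroid lies within `depth_um` of
#' the lumen boundary polyline. The band is defined in the imaged (diastolic)
#' reference configuration so membership cannot change between load steps.
#'
#' @param mesh an [generate_mesh()] result.
#' @param depth_um band depth in micrometres (default 50).
#' @return integer vector of element ids.
#' @export
extract_superficial_set <- function(mesh, depth_um = 50) {
  if (depth_um <= 0) stop("superficial band depth must be positive")
  cen <- element_centroids(mesh)
  lum <- mesh$nodes[mesh$lumen_loop, , drop = FALSE]
  d <- dist_to_polyline(cen[, 1], cen[, 2], lum)
  ids <- which(d <= depth_um / 1000)
  if (!length(ids))
    stop("no element centroid within ", depth_um,
         " um of the lumen: mesh too coarse for the superficial band")
  ids
}

element_centroids <- function(mesh) {
  cbind((mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] +
           mesh$nodes[mesh$tri[, 3], 1]) / 3,
        (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
           mesh$nodes[mesh$tri[, 3], 2]) / 3)
}

element_areas <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tri
  ((n[t[, 2], 1] - n[t[, 1], 1]) * (n[t[, 3], 2] - n[t[, 1], 2]) -
    (n[t[, 2], 2] - n[t[, 1], 2]) * (n[t[, 3], 1] - n[t[, 1], 1])) / 2
}

# longest edge of each element
element_max_edge <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tri
  e1 <- sqrt(rowSums((n[t[, 2], ] - n[t[, 1], ])^2))
  e2 <- sqrt(rowSums((n[t[, 3], ] - n[t[, 2], ])^2))
  e3 <- sqrt(rowSums((n[t[, 1], ] - n[t[, 3], ])^2))
  pmax(e1, e2, e3)
}

# minimum interior angle (degrees) of each element
element_min_angle <- function(mesh) {
  n <- mesh$nodes; t <- mesh$tri
  l1 <- rowSums((n[t[, 2], ] - n[t[, 1], ])^2)
  l2 <- rowSums((n[t[, 3], ] - n[t[, 2], ])^2)
  l3 <- rowSums((n[t[, 1], ] - n[t[, 3], ])^2)
  ang <- function(a2, b2, c2)
    acos(pmin(pmax((a2 + b2 - c2) / (2 * sqrt(a2 * b2)), -1), 1))
  a1 <- ang(l1, l3, l2); a2_ <- ang(l1, l2, l3); a3 <- pi - a1 - a2_
  pmin(a1, a2_, a3) * 180 / pi
}

#' Mesh quality and conformity summary
#'
#' @param mesh an [generate_mesh()] result.
#' @return list with total/per-region areas, superficial maximum edge length,
#'   minimum interior angle and element count.
#' @export
mesh_quality <- function(mesh) {
  ar <- element_areas(mesh)
  list(n_elements = nrow(mesh$tri),
       n_nodes = nrow(mesh$nodes),
       total_area = sum(ar),
       region_areas = tapply(ar, mesh$region, sum),
       superficial_max_edge = max(element_max_edge(mesh)[mesh$superficial]),
       min_angle_deg = min(element_min_angle(mesh)))
}
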