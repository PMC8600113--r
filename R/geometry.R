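#' Build the layered multi-material geometry of a cross-section
#'
#' Constructs the three-layer geometric model: the intima is the annular
#' region between lumen and IEL, with lipid and calcium regions clipped to it
#' (fibrous tissue is the remainder); the media is the band between the IEL
#' and its uniform outward offset by the media thickness; the adventitia is
#' the next band. When lipid and calcium regions overlap, calcium wins
#' (calcium delineation is the higher-confidence reading on OCT); the overlap
#' reassignment is reported as a message.
#'
#' The geometry is star-shaped with respect to the lumen centroid (the
#' origin after normalization); region bookkeeping and area quadrature use a
#' polar decomposition about that point, which holds for vessel cross-sections.
#'
#' @param cs a [cross_section()].
#' @param n_quad number of angular quadrature rays for region areas
#'   (default 2048).
#' @return object of class `"layered_geometry"`: contours `lumen`, `iel`,
#'   `media_outer`, `adventitia_outer` (= outer boundary), the clipped
#'   `regions`, and an `areas` list with components `intima_fibrous`,
#'   `intima_lipid`, `intima_calcium`, `media`, `adventitia`.
#' @export
build_layered_geometry <- function(cs, n_quad = 2048L) {
  lumen <- cs$lumen; iel <- cs$iel
  media_outer <- offset_contour(iel, cs$media_thickness, n = 192L)
  adventitia_outer <- offset_contour(media_outer, cs$adventitia_thickness, n = 192L)

  theta <- seq(0, 2 * pi, length.out = n_quad + 1L)[-(n_quad + 1L)]
  r_lum <- contour_radius_at(lumen, theta)
  r_iel <- contour_radius_at(iel, theta)
  if (anyNA(r_lum) || anyNA(r_iel))
    stop("lumen/IEL contours are not star-shaped about the lumen centroid")
  if (any(r_iel <= r_lum))
    stop("lumen and IEL contours intersect")

  # radial intervals of each region along every quadrature ray, clipped to
  # the intima; calcium takes precedence on overlap
  clip_iv <- function(iv, lo, hi) {
    if (!length(iv)) return(iv)
    iv <- matrix(iv, ncol = 2L)
    iv[, 1] <- pmax(iv[, 1], lo); iv[, 2] <- pmin(iv[, 2], hi)
    iv[iv[, 1] < iv[, 2], , drop = FALSE]
  }
  pair_iv <- function(r) {
    if (length(r) < 2L) return(matrix(numeric(0), ncol = 2L))
    if (length(r) %% 2L) r <- r[-length(r)]
    matrix(r, ncol = 2L, byrow = TRUE)
  }
  labs <- vapply(cs$regions, function(r) r$label, "")
  calc_iv <- lipid_iv <- rep(list(matrix(numeric(0), ncol = 2L)), n_quad)
  raw_area <- stats::setNames(numeric(length(cs$regions)), labs)
  for (k in seq_along(cs$regions)) {
    cr <- ray_crossings(theta, cs$regions[[k]]$boundary)
    raw_area[k] <- abs(polygon_area(cs$regions[[k]]$boundary))
    for (i in seq_len(n_quad)) {
      iv <- clip_iv(pair_iv(cr[[i]]), r_lum[i], r_iel[i])
      if (!nrow(iv)) next
      if (labs[k] == "calcium") calc_iv[[i]] <- rbind(calc_iv[[i]], iv)
      else lipid_iv[[i]] <- rbind(lipid_iv[[i]], iv)
    }
  }
  # subtract calcium intervals from lipid intervals (calcium wins)
  iv_subtract <- function(a, b) {
    if (!nrow(a) || !nrow(b)) return(a)
    out <- matrix(numeric(0), ncol = 2L)
    for (j in seq_len(nrow(a))) {
      segs <- matrix(a[j, ], ncol = 2L)
      for (i in seq_len(nrow(b))) {
        keep <- matrix(numeric(0), ncol = 2L)
        for (s in seq_len(nrow(segs))) {
          lo <- segs[s, 1]; hi <- segs[s, 2]
          if (b[i, 2] <= lo || b[i, 1] >= hi) keep <- rbind(keep, c(lo, hi))
          else {
            if (b[i, 1] > lo) keep <- rbind(keep, c(lo, b[i, 1]))
            if (b[i, 2] < hi) keep <- rbind(keep, c(b[i, 2], hi))
          }
        }
        segs <- keep
        if (!nrow(segs)) break
      }
      out <- rbind(out, segs)
    }
    out
  }
  overlap_flag <- FALSE
  lipid_iv_pre <- lipid_iv
  for (i in seq_len(n_quad)) {
    if (nrow(lipid_iv[[i]]) && nrow(calc_iv[[i]])) {
      sub <- iv_subtract(lipid_iv[[i]], calc_iv[[i]])
      if (!isTRUE(all.equal(sum(lipid_iv[[i]][, 2] - lipid_iv[[i]][, 1]),
                            sum(sub[, 2] - sub[, 1]))))
        overlap_flag <- TRUE
      lipid_iv[[i]] <- sub
    }
  }
  if (overlap_flag)
    message("lipid/calcium overlap detected: overlapping area assigned to calcium")

  dtheta <- 2 * pi / n_quad
  iv_area <- function(ivl) {
    sum(vapply(ivl, function(iv)
      if (nrow(iv)) sum(iv[, 2]^2 - iv[, 1]^2) / 2 else 0, 0)) * dtheta
  }
  area_lipid <- iv_area(lipid_iv)
  area_calc <- iv_area(calc_iv)
  area_intima <- polygon_area(iel) - polygon_area(lumen)
  tot_regions <- area_lipid + area_calc
  # clip warning compares against the pre-overlap clipped areas so that
  # calcium-over-lipid reassignment alone does not look like clipping
  clipped_total <- iv_area(lipid_iv_pre) + area_calc
  raw_total <- sum(raw_area)
  if (raw_total > 0 && clipped_total < raw_total * (1 - 1e-3))
    warning(sprintf("plaque regions clipped to the intima: %.3f of %.3f mm^2 retained",
                    clipped_total, raw_total))

  areas <- list(
    intima_fibrous = area_intima - area_lipid - area_calc,
    intima_lipid = area_lipid,
    intima_calcium = area_calc,
    media = polygon_area(media_outer) - polygon_area(iel),
    adventitia = polygon_area(adventitia_outer) - polygon_area(media_outer))
  if (areas$intima_fibrous < -1e-3 * area_intima)
    stop("plaque regions exceed the intimal area; check region contours")

  structure(list(lumen = lumen, iel = iel, media_outer = media_outer,
                 adventitia_outer = adventitia_outer,
                 regions = cs$regions, areas = areas,
                 media_thickness = cs$media_thickness,
                 adventitia_thickness = cs$adventitia_thickness,
                 frame_id = cs$frame_id,
                 pullback_position = cs$pullback_position),
            class = "layered_geometry")
}

#' @export
print.layered_geometry <- function(x, ...) {
  a <- x$areas
  cat(sprintf(paste0("<layered_geometry> frame %d: intima %.2f mm^2 ",
                     "(fibrous %.2f, lipid %.2f, calcium %.2f), media %.2f, adventitia %.2f\n"),
              x$frame_id, a$intima_fibrous + a$intima_lipid + a$intima_calcium,
              a$intima_fibrous, a$intima_lipid, a$intima_calcium,
              a$media, a$adventitia))
  invisible(x)
}

# Classify points into tissue labels within a layered geometry.
classify_points <- function(geom, px, py) {
  lab <- rep(NA_character_, length(px))
  in_iel <- point_in_polygon(px, py, geom$iel)
  in_med <- point_in_polygon(px, py, geom$media_outer)
  lab[!in_iel & in_med] <- "media"
  lab[!in_iel & !in_med] <- "adventitia"
  idx <- which(in_iel)
  if (length(idx)) {
    lab[idx] <- "fibrous"
    for (r in geom$regions) {
      if (r$label != "lipid") next
      sel <- idx[point_in_polygon(px[idx], py[idx], r$boundary)]
      lab[sel] <- "lipid"
    }
    for (r in geom$regions) {
      if (r$label != "calcium") next
      sel <- idx[point_in_polygon(px[idx], py[idx], r$boundary)]
      lab[sel] <- "calcium"
    }
  }
  lab
}

#' Plaque burden of a cross-section
#'
#' Percent of the IEL area occupied by plaque:
#' `100 * (area(iel) - area(lumen)) / area(iel)`.
#'
#' @param lumen,iel [contour()]s with the lumen nested inside the IEL.
#' @return plaque burden in percent.
#' @export
compute_plaque_burden <- function(lumen, iel) {
  a_l <- abs(polygon_area(lumen)); a_i <- abs(polygon_area(iel))
  if (a_i < a_l)
    stop("IEL area is smaller than lumen area; contours are not nested")
  if (!all(point_in_polygon(lumen[, 1], lumen[, 2], iel)) &&
      a_i > a_l)  # identical contours are allowed (zero burden)
    if (polyline_min_distance(lumen, iel) > 1e-9)
      stop("lumen contour is not inside the IEL contour")
  100 * (a_i - a_l) / a_i
}

#' Fibrous cap thickness
#'
#' Minimum Euclidean distance between the lumen contour and a lipid region
#' boundary, in micrometres. Undefined (NA) for frames without a lipid pool,
#' mirroring how purely fibrous frames carry no cap measurement.
#'
#' @param lumen a [contour()].
#' @param lipid a [plaque_region()] with label `"lipid"`, or `NULL`.
#' @return cap thickness in micrometres, or `NA_real_` when no lipid region is
#'   present.
#' @export
measure_cap_thickness <- function(lumen, lipid) {
  if (is.null(lipid)) return(NA_real_)
  if (inherits(lipid, "plaque_region")) {
    if (lipid$label != "lipid") stop("cap thickness is defined against a lipid region")
    lipid <- lipid$boundary
  }
  1000 * polyline_min_distance(lumen, lipid)
}

#' Complete a partially visible IEL contour by ellipse fitting
#'
#' When attenuation hides part of the IEL, the visible arc can be extrapolated
#' by a least-squares ellipse (direct algebraic fit), provided at least half
#' the circumference is visible; otherwise the adjacent-frame IEL should be
#' used instead.
#'
#' @param visible_arc two-column matrix of arc points (open polyline), mm.
#' @param method only `"ellipse_fit"` is implemented.
#' @param n number of vertices of the completed contour.
#' @return a closed [contour()] along the fitted ellipse.
#' @export
complete_partial_iel <- function(visible_arc, method = "ellipse_fit", n = 128L) {
  method <- match.arg(method, "ellipse_fit")
  pts <- as.matrix(visible_arc)
  if (nrow(pts) < 8L) stop("need at least 8 arc points for an ellipse fit")
  fit <- fit_ellipse(pts)
  # arc coverage is judged about the fitted center (the point cloud centroid
  # sits inside the arc and would overestimate the span)
  ang <- atan2(pts[, 2] - fit$center[2], pts[, 1] - fit$center[1])
  span <- .angular_span(ang)
  if (span < pi)
    stop(sprintf(paste0("visible IEL arc spans only %.0f degrees (< 180); ",
                        "use the adjacent frame's IEL instead"), span * 180 / pi))
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ca <- cos(fit$angle); sa <- sin(fit$angle)
  x <- fit$center[1] + fit$a * cos(t) * ca - fit$b * sin(t) * sa
  y <- fit$center[2] + fit$a * cos(t) * sa + fit$b * sin(t) * ca
  out <- contour(cbind(x, y))
  attr(out, "fit") <- fit
  out
}

# Angular span covered by a set of angles (largest covered circular range).
.angular_span <- function(ang) {
  a <- sort(ang %% (2 * pi))
  gaps <- diff(c(a, a[1] + 2 * pi))
  2 * pi - max(gaps)
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct algebraic ellipse fit (Halir-Flusser form of the
#' Fitzgibbon method): minimizes the algebraic distance subject to the
#' ellipse constraint 4AC - B^2 = 1.
#'
#' @param pts two-column matrix of points.
#' @return list with `center` (x, y), semi-axes `a` >= `b`, orientation
#'   `angle` (radians), and the conic coefficients `coef`
#'   (A, B, C, D, E, F for Ax^2+Bxy+Cy^2+Dx+Ey+F=0).
#' @export
fit_ellipse <- function(pts) {
  pts <- as.matrix(pts)
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y); sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  a1 <- Re(ev$vectors[, which(cond > 0)[1]])
  if (!length(a1)) stop("ellipse fit failed (no admissible eigenvector)")
  coef_s <- c(a1, Tm %*% a1)   # A B C D E F in scaled coordinates
  # unscale: substitute xs = (x-mx)/sc, ys = (y-my)/sc
  A <- coef_s[1] / sc^2; B <- coef_s[2] / sc^2; C <- coef_s[3] / sc^2
  D <- -2 * coef_s[1] * mx / sc^2 - coef_s[2] * my / sc^2 + coef_s[4] / sc
  E <- -coef_s[2] * mx / sc^2 - 2 * coef_s[3] * my / sc^2 + coef_s[5] / sc
  Fc <- coef_s[1] * mx^2 / sc^2 + coef_s[2] * mx * my / sc^2 +
    coef_s[3] * my^2 / sc^2 - coef_s[4] * mx / sc - coef_s[5] * my / sc +
    coef_s[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # center the conic: x' M2 x' + Q(c) = 0 with M2 the quadratic form;
  # semi-axes are sqrt(-Q/lambda_i) along the eigenvectors of M2
  Qc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M2, symmetric = TRUE)
  ax <- sqrt(pmax(-Qc / ev$values, 0))
  if (any(!is.finite(ax)) || any(ax <= 0)) stop("ellipse fit failed (degenerate conic)")
  major <- which.max(ax)
  list(center = c(cx, cy), a = ax[major], b = min(ax),
       angle = atan2(ev$vectors[2, major], ev$vectors[1, major]),
       coef = c(A, B, C, D, E, Fc))
}
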