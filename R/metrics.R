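#' Von Mises equivalent stress
#'
#' \eqn{\sigma_{vm} = \sqrt{\tfrac{3}{2}\,dev(\sigma):dev(\sigma)}}, including
#' the out-of-plane (plane-strain) component.
#'
#' @param sigma 3x3 symmetric Cauchy stress tensor, kPa.
#' @param tol asymmetry tolerance.
#' @return equivalent stress, kPa.
#' @export
von_mises <- function(sigma, tol = 1e-9) {
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == c(3L, 3L))) stop("sigma must be 3x3")
  if (max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma))))
    stop("stress tensor is not symmetric")
  s <- sigma - diag(rep(sum(diag(sigma)) / 3, 3L))
  sqrt(1.5 * sum(s * s))
}

#' Cyclic change in plaque structural stress
#'
#' The maximal superficial von Mises stress at the step of maximal pressure
#' load: the stress metric of the cyclic loading analysis. Stresses are
#' evaluated at element centroids; the superficial set holds the elements
#' within 50 um of the lumen in the reference configuration.
#'
#' @param solution a [solve_cycle()] result (or its list of steps).
#' @param superficial integer element ids of the superficial band (defaults
#'   to the solution mesh's own set).
#' @return list with `dpss` (kPa), `location` (x, y of the critical element
#'   centroid, mm), `element` (element id) and `peak_load` (kPa).
#' @export
compute_dpss <- function(solution, superficial = NULL) {
  steps <- if (inherits(solution, "pss_solution")) solution$steps else solution
  if (is.null(superficial)) superficial <- solution$mesh$superficial
  if (!length(superficial)) stop("empty superficial element set")
  loads <- vapply(steps, function(s) s$load, 0)
  st <- steps[[which.max(loads)]]
  vm <- st$von_mises[superficial]
  k <- which.max(vm)
  eid <- superficial[k]
  cen <- element_centroids(solution$mesh)
  list(dpss = vm[k], location = cen[eid, ], element = eid,
       peak_load = max(loads))
}

#' Lumen diameter change over the cycle
#'
#' Computes the effective (area-equivalent) lumen diameter
#' \eqn{d = 2\sqrt{A/\pi}} of the deformed lumen at every load step; the
#' lumen diameter change is `max(d) - min(d)` over the cycle and its relative
#' version is `100 * ldc / min(d)`. In this elastic quasi-static model the
#' minimal diameter occurs at zero load (diastole) and the maximal at peak
#' load; both are always present as steps.
#'
#' @param solution a [solve_cycle()] result (or its list of steps).
#' @return list with `ldc` (mm), `ldc_percent` (%), `d_min`, `d_max` (mm).
#' @export
compute_ldc <- function(solution) {
  steps <- if (inherits(solution, "pss_solution")) solution$steps else solution
  if (length(steps) < 2L) stop("need at least two steps (zero and peak load)")
  d <- vapply(steps, function(s) {
    a <- polygon_area(s$deformed_lumen)
    if (!is.finite(a) || a <= 0) stop("degenerate deformed lumen polygon")
    2 * sqrt(a / pi)
  }, 0)
  ldc <- max(d) - min(d)
  list(ldc = ldc, ldc_percent = 100 * ldc / min(d),
       d_min = min(d), d_max = max(d))
}

#' Full per-frame stress metrics
#'
#' Bundles the endpoint quantities of one analyzed cross-section: the cyclic
#' plaque structural stress change, lumen diameter change (absolute and
#' percent), plaque burden and fibrous cap thickness.
#'
#' @param solution a [solve_cycle()] result.
#' @param cs the analyzed [cross_section()].
#' @param position_label optional marker label (PR/PS/MLA/DS/DR).
#' @return object of class `"stress_metrics"` (also a one-row data.frame via
#'   [as.data.frame.stress_metrics()]).
#' @export
stress_metrics <- function(solution, cs, position_label = NA_character_) {
  dp <- compute_dpss(solution)
  ld <- compute_ldc(solution)
  lipids <- Filter(function(r) r$label == "lipid", cs$regions)
  cap <- if (length(lipids))
    min(vapply(lipids, function(r) measure_cap_thickness(cs$lumen, r), 0))
  else NA_real_
  structure(list(frame_id = cs$frame_id,
                 position_label = position_label,
                 dpss = dp$dpss, dpss_location = dp$location,
                 dpss_element = dp$element,
                 ldc = ld$ldc, ldc_percent = ld$ldc_percent,
                 plaque_burden = compute_plaque_burden(cs$lumen, cs$iel),
                 cap_thickness = cap,
                 peak_load = dp$peak_load),
            class = "stress_metrics")
}

#' @export
print.stress_metrics <- function(x, ...) {
  cat(sprintf(paste0("<stress_metrics> frame %d (%s): dPSS %.2f kPa, ",
                     "LDC %.3f mm (%.2f%%), burden %.1f%%, cap %s um\n"),
              x$frame_id, x$position_label, x$dpss, x$ldc, x$ldc_percent,
              x$plaque_burden,
              ifelse(is.na(x$cap_thickness), "-",
                     sprintf("%.0f", x$cap_thickness))))
  invisible(x)
}

#' @export
#' @rdname stress_metrics
#' @param x a `stress_metrics` object; `...` ignored.
as.data.frame.stress_metrics <- function(x, ...) {
  data.frame(frame_id = x$frame_id, position_label = x$position_label,
             dpss_kpa = x$dpss, ldc_mm = x$ldc, ldc_percent = x$ldc_percent,
             plaque_burden_pct = x$plaque_burden,
             cap_thickness_um = x$cap_thickness,
             peak_load_kpa = x$peak_load,
             stringsAsFactors = FALSE)
}
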