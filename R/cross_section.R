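#' Plaque region
#'
#' A labeled intimal plaque component. Fibrous tissue is the background
#' intimal material, so only lipid and calcium regions are represented
#' explicitly; anything of the intima not covered by a region is fibrous.
#'
#' @param label `"lipid"` or `"calcium"`.
#' @param boundary a [contour()] outlining the component.
#' @return object of class `"plaque_region"`.
#' @export
plaque_region <- function(label, boundary) {
  label <- match.arg(label, c("lipid", "calcium"))
  if (!inherits(boundary, "contour")) boundary <- contour(boundary)
  structure(list(label = label, boundary = boundary), class = "plaque_region")
}

#' Vessel cross-section
#'
#' The full morphologic description of one imaging frame: lumen and internal
#' elastic lamina (IEL) contours, labeled intimal plaque regions, and the
#' media/adventitia thicknesses measured on the frame (or taken from an
#' adjacent frame when the outer wall is not visible).
#'
#' Coordinates are normalized on construction: the lumen centroid is moved to
#' the origin and both contours and all region boundaries are translated with
#' it.
#'
#' @param frame_id integer frame identifier.
#' @param pullback_position position of the frame along the pullback, mm.
#' @param lumen,iel [contour()]s; the lumen must lie strictly inside the IEL.
#' @param regions list of [plaque_region()]s (may be empty).
#' @param media_thickness,adventitia_thickness layer thicknesses in mm (> 0).
#' @return object of class `"cross_section"`.
#' @export
cross_section <- function(frame_id, pullback_position, lumen, iel,
                          regions = list(), media_thickness,
                          adventitia_thickness) {
  if (!inherits(lumen, "contour")) lumen <- contour(lumen)
  if (!inherits(iel, "contour")) iel <- contour(iel)
  regions <- lapply(regions, function(r)
    if (inherits(r, "plaque_region")) r else plaque_region(r$label, r$boundary))
  if (!is.finite(media_thickness) || media_thickness <= 0)
    stop("media_thickness must be positive")
  if (!is.finite(adventitia_thickness) || adventitia_thickness <= 0)
    stop("adventitia_thickness must be positive")

  ctr <- polygon_centroid(lumen)
  shift <- function(m) {
    out <- unclass(m); out[, 1] <- out[, 1] - ctr[1]; out[, 2] <- out[, 2] - ctr[2]
    contour(out, check = FALSE)
  }
  lumen <- shift(lumen); iel <- shift(iel)
  regions <- lapply(regions, function(r) plaque_region(r$label, shift(r$boundary)))

  if (!all(point_in_polygon(lumen[, 1], lumen[, 2], iel)))
    stop("lumen contour must lie strictly inside the IEL contour")
  if (polygon_area(iel) <= polygon_area(lumen))
    stop("IEL area must exceed lumen area")

  structure(list(frame_id = as.integer(frame_id),
                 pullback_position = as.numeric(pullback_position),
                 lumen = lumen, iel = iel, regions = regions,
                 media_thickness = media_thickness,
                 adventitia_thickness = adventitia_thickness),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> frame %d @ %.2f mm: lumen %.2f mm^2, IEL %.2f mm^2, %d region(s)\n",
              x$frame_id, x$pullback_position, polygon_area(x$lumen),
              polygon_area(x$iel), length(x$regions)))
  invisible(x)
}

#' Write a cross-section to a JSON document
#'
#' One document per frame with keys `frame_id`, `pullback_position_mm`,
#' `lumen`, `iel`, `regions`, `media_thickness_mm`, `adventitia_thickness_mm`;
#' contour points are `[x, y]` pairs in mm.
#'
#' @param cs a [cross_section()].
#' @param path output file path.
#' @export
write_cross_section <- function(cs, path) {
  doc <- list(
    frame_id = cs$frame_id,
    pullback_position_mm = cs$pullback_position,
    lumen = unname(apply(unclass(cs$lumen), 1, function(p) c(p[1], p[2]), simplify = FALSE)),
    iel = unname(apply(unclass(cs$iel), 1, function(p) c(p[1], p[2]), simplify = FALSE)),
    regions = lapply(cs$regions, function(r) list(
      label = r$label,
      points = unname(apply(unclass(r$boundary), 1, function(p) c(p[1], p[2]),
                            simplify = FALSE)))),
    media_thickness_mm = cs$media_thickness,
    adventitia_thickness_mm = cs$adventitia_thickness)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cross-section from a JSON document
#'
#' @param path file written by [write_cross_section()] (or following the same
#'   schema).
#' @return a [cross_section()].
#' @export
read_cross_section <- function(path) {
  doc <- jsonlite::read_json(path)
  as_pts <- function(lst)
    do.call(rbind, lapply(lst, function(p) c(p[[1]], p[[2]])))
  regs <- lapply(doc$regions, function(r)
    plaque_region(r$label, contour(as_pts(r$points))))
  cross_section(doc$frame_id, doc$pullback_position_mm,
                contour(as_pts(doc$lumen)), contour(as_pts(doc$iel)), regs,
                doc$media_thickness_mm, doc$adventitia_thickness_mm)
}
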