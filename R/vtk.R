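#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' Unstructured-grid export of the triangulated cross-section for external
#' viewers, with region labels and the superficial flag as cell data and any
#' number of additional per-element scalar fields.
#'
#' @param mesh an [generate_mesh()] result.
#' @param path output `.vtk` file.
#' @param cell_data named list of numeric per-element vectors (e.g. von Mises
#'   stress); `point_data` named list of per-node vectors or N x 2
#'   displacement matrices.
#' @export
write_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  writeLines(c("# vtk DataFile Version 3.0",
               "plaquestress cross-section", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)

  writeLines(sprintf("CELL_DATA %d", m), con)
  region_codes <- match(mesh$region,
                        c("fibrous", "lipid", "calcium", "media", "adventitia"))
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", region_codes), con)
  sup <- integer(m); sup[mesh$superficial] <- 1L
  writeLines(c("SCALARS superficial int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", sup), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", cell_data[[nm]]), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.9g %.9g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.9g", v), con)
      }
    }
  }
  invisible(path)
}

#' Export a layered geometry as WKT polygons
#'
#' Writes one well-known-text POLYGON per boundary (lumen, IEL, media outer,
#' adventitia outer, and each plaque region) for inspection in GIS-style
#' viewers.
#'
#' @param geom a [build_layered_geometry()] result.
#' @param path output text file.
#' @export
write_geometry_wkt <- function(geom, path) {
  wkt <- function(pts) {
    pts <- unclass(pts)
    pts <- rbind(pts, pts[1L, ])
    sprintf("POLYGON ((%s))",
            paste(sprintf("%.6f %.6f", pts[, 1], pts[, 2]), collapse = ", "))
  }
  lines <- c(paste0("lumen\t", wkt(geom$lumen)),
             paste0("iel\t", wkt(geom$iel)),
             paste0("media_outer\t", wkt(geom$media_outer)),
             paste0("adventitia_outer\t", wkt(geom$adventitia_outer)))
  for (r in geom$regions)
    lines <- c(lines, paste0(r$label, "\t", wkt(r$boundary)))
  writeLines(lines, path)
  invisible(path)
}
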