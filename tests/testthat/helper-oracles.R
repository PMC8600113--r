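# independent geometry oracles via the system Python (shapely, scikit-image);
# used only as cross-checks, never as the implementation

run_python <- function(script, input = NULL) {
  tf <- tempfile(fileext = ".py")
  writeLines(script, tf)
  on.exit(unlink(tf))
  out <- suppressWarnings(system2("python", tf, stdout = TRUE, stderr = TRUE,
                                  input = input))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}

pts_csv <- function(pts) paste(sprintf("%.12g,%.12g", pts[, 1], pts[, 2]),
                               collapse = ";")

# polygon area via shapely
shapely_area <- function(pts) {
  out <- run_python(sprintf("
from shapely.geometry import Polygon
pts = [tuple(map(float, p.split(','))) for p in '%s'.split(';')]
print(repr(Polygon(pts).area))
", pts_csv(pts)))
  as.numeric(out[length(out)])
}

# area of polygon A clipped to the annular region between lumen and iel
shapely_clip_area <- function(poly, lumen, iel) {
  out <- run_python(sprintf("
from shapely.geometry import Polygon
def rd(s):
    return Polygon([tuple(map(float, p.split(','))) for p in s.split(';')])
poly, lumen, iel = rd('%s'), rd('%s'), rd('%s')
print(repr(poly.intersection(iel.difference(lumen)).area))
", pts_csv(poly), pts_csv(lumen), pts_csv(iel)))
  as.numeric(out[length(out)])
}

# buffered (offset) polygon area via shapely, round joins
shapely_buffer_area <- function(pts, t) {
  out <- run_python(sprintf("
from shapely.geometry import Polygon
pts = [tuple(map(float, p.split(','))) for p in '%s'.split(';')]
print(repr(Polygon(pts).buffer(%.12g, quad_segs=64).area))
", pts_csv(pts), t))
  as.numeric(out[length(out)])
}

# direct algebraic ellipse fit via scikit-image EllipseModel
skimage_ellipse_fit <- function(pts) {
  out <- run_python(sprintf("
import numpy as np
from skimage.measure import EllipseModel
pts = np.array([tuple(map(float, p.split(','))) for p in '%s'.split(';')])
m = EllipseModel()
assert m.estimate(pts)
xc, yc, a, b, th = [float(v) for v in m.params]
print(xc, yc, max(a, b), min(a, b))
", pts_csv(pts)))
  as.numeric(strsplit(out[length(out)], " +")[[1]])
}
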