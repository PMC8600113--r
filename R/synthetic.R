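#' Synthetic cross-section specification
#'
#' Parameters of an idealized coronary cross-section: a mildly perturbed
#' circular lumen, an eccentric wall (thicker on one side for eccentricity
#' > 0), an optional lipid crescent at a prescribed fibrous cap thickness,
#' and an optional calcium arc placed deeper in the intima.
#'
#' @param lumen_radius lumen radius, mm.
#' @param wall_thickness maximal intima (lumen-to-IEL) thickness, mm.
#' @param eccentricity wall eccentricity in \[0, 1): 0 gives a concentric
#'   wall; larger values thin the wall opposite the plaque.
#' @param lipid_arc angular extent of the lipid pool in degrees (0 = none).
#' @param cap_thickness fibrous cap thickness in micrometres.
#' @param calcium_arc angular extent of the calcium arc in degrees (0 = none).
#' @param media_thickness,adventitia_thickness outer layer thicknesses, mm.
#' @param seed integer seed making the section deterministic.
#' @return object of class `"section_spec"`.
#' @export
section_spec <- function(lumen_radius = 1.2, wall_thickness = 0.8,
                         eccentricity = 0.4, lipid_arc = 0,
                         cap_thickness = 150, calcium_arc = 0,
                         media_thickness = 0.2, adventitia_thickness = 0.25,
                         seed = 1L) {
  if (lumen_radius <= 0 || wall_thickness <= 0) stop("radii must be positive")
  if (eccentricity < 0 || eccentricity >= 1) stop("eccentricity must be in [0, 1)")
  if (lipid_arc < 0 || lipid_arc >= 360) stop("lipid_arc must be in [0, 360)")
  if (calcium_arc < 0 || calcium_arc >= 360) stop("calcium_arc must be in [0, 360)")
  if (cap_thickness >= wall_thickness * 1000)
    stop("cap_thickness must be smaller than the wall thickness")
  if (lipid_arc > 0 && cap_thickness < 20)
    stop("cap_thickness below 20 um is not resolvable")
  structure(list(lumen_radius = lumen_radius, wall_thickness = wall_thickness,
                 eccentricity = eccentricity, lipid_arc = lipid_arc,
                 cap_thickness = cap_thickness, calcium_arc = calcium_arc,
                 media_thickness = media_thickness,
                 adventitia_thickness = adventitia_thickness,
                 seed = as.integer(seed)),
            class = "section_spec")
}

# run `expr` under a local RNG seeded with `seed`, restoring the global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth periodic perturbation (low-order Fourier modes), amplitude `amp`
.fourier_bump <- function(theta, amp, n_modes = 3L) {
  out <- numeric(length(theta))
  for (k in seq_len(n_modes)) {
    out <- out + stats::rnorm(1, 0, amp / n_modes) * cos(k * theta) +
      stats::rnorm(1, 0, amp / n_modes) * sin(k * theta)
  }
  out
}

#' Generate an idealized synthetic cross-section
#'
#' Builds a [cross_section()] from a [section_spec()]: lumen and IEL as
#' smoothly perturbed circles (wall thickness maximal at angle 0 for
#' eccentric specs), a lipid crescent whose inner boundary follows the lumen
#' at exactly the requested cap thickness (offset along the lumen normals),
#' and an optional calcium arc centered at 120 degrees placed deeper in the
#' intima. Deterministic for a fixed spec seed.
#'
#' @param spec a [section_spec()].
#' @param frame_id,pullback_position frame bookkeeping for the result.
#' @param n_vertices contour resolution.
#' @return a [cross_section()].
#' @export
make_section <- function(spec, frame_id = 1L, pullback_position = 0,
                         n_vertices = 160L) {
  with_seed(spec$seed, {
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    rl <- spec$lumen_radius * (1 + .fourier_bump(theta, 0.015))
    lumen <- contour(cbind(rl * cos(theta), rl * sin(theta)))
    # wall thickness profile: maximal at theta = 0, thinned opposite
    e <- spec$eccentricity
    wt <- spec$wall_thickness * (1 + e * cos(theta)) / (1 + e)
    min_wall <- 0.12
    wt <- pmax(wt, min_wall)
    ri <- rl + wt * (1 + .fourier_bump(theta, 0.01))
    iel <- contour(cbind(ri * cos(theta), ri * sin(theta)))

    regions <- list()
    if (spec$lipid_arc > 0) {
      regions <- c(regions, list(.make_crescent(
        lumen, iel, label = "lipid",
        arc_deg = spec$lipid_arc, center_deg = 0,
        inner_gap = spec$cap_thickness / 1000,
        outer_margin = 0.08)))
    }
    if (spec$calcium_arc > 0) {
      regions <- c(regions, list(.make_crescent(
        lumen, iel, label = "calcium",
        arc_deg = spec$calcium_arc, center_deg = 120,
        inner_gap = max(spec$cap_thickness / 1000, 0.12),
        outer_margin = 0.05)))
    }
    cross_section(frame_id, pullback_position, lumen, iel, regions,
                  spec$media_thickness, spec$adventitia_thickness)
  })
}

# Crescent-shaped intimal region: inner boundary at distance `inner_gap`
# along the lumen outward normals over the angular window, outer boundary a
# fraction of the way to the IEL (leaving `outer_margin` mm), ends tapered.
.make_crescent <- function(lumen, iel, label, arc_deg, center_deg,
                           inner_gap, outer_margin) {
  n_dense <- 256L
  off <- offset_contour(lumen, inner_gap, n = n_dense)
  ang_off <- atan2(off[, 2], off[, 1])
  half <- arc_deg / 2 * pi / 180
  c0 <- center_deg * pi / 180
  d <- ((ang_off - c0 + pi) %% (2 * pi)) - pi     # signed angle from center
  sel <- which(abs(d) <= half)
  if (length(sel) < 6L)
    stop("region arc too small to build (", label, ")")
  sel <- sel[order(d[sel])]
  inner <- off[sel, , drop = FALSE]
  th_in <- atan2(inner[, 2], inner[, 1])
  r_in <- sqrt(rowSums(inner^2))
  r_iel <- contour_radius_at(iel, th_in)
  r_out_max <- r_iel - outer_margin
  # taper: full thickness at the center, closing to the inner boundary at ends
  frac <- abs(((th_in - c0 + pi) %% (2 * pi)) - pi) / half
  taper <- cos(pmin(frac, 1) * pi / 2)^0.75
  r_out <- r_in + pmax(r_out_max - r_in, 0.02) * taper
  r_out <- pmax(r_out, r_in + 0.015)
  outer <- cbind(r_out * cos(th_in), r_out * sin(th_in))
  poly <- rbind(inner, outer[rev(seq_len(nrow(outer))), , drop = FALSE])
  plaque_region(label, contour(poly, check = FALSE))
}

#' Generate a synthetic paired pressure tracing
#'
#' Smooth periodic aortic waveform built from two harmonics (systolic peak
#' plus dicrotic bump), normalized so the stated systolic and diastolic
#' values are attained exactly; the distal channel is the aortic one scaled
#' by `1 - gradient` with optional Gaussian noise. Deterministic per seed.
#'
#' @param systolic,diastolic aortic bounds, mmHg.
#' @param hr heart rate, beats per minute.
#' @param n_beats number of beats.
#' @param gradient translesional drop as a fraction of Pa in \[0, 0.9\].
#' @param noise_sd Gaussian noise on the distal channel, mmHg.
#' @param seed integer seed.
#' @param fs sampling frequency, Hz.
#' @return a [pressure_tracing()].
#' @export
make_pressure_tracing <- function(systolic = 120, diastolic = 80, hr = 75,
                                  n_beats = 3L, gradient = 0.1, noise_sd = 0,
                                  seed = 1L, fs = 100) {
  if (systolic <= diastolic || diastolic <= 0)
    stop("need systolic > diastolic > 0")
  if (gradient < 0 || gradient > 0.9) stop("gradient must be in [0, 0.9]")
  period <- 60 / hr
  time <- seq(0, n_beats * period, by = 1 / fs)
  phase <- (time / period) %% 1
  raw <- sin(2 * pi * phase - 0.9) + 0.45 * sin(4 * pi * phase - 0.2)
  w <- (raw - min(raw)) / (max(raw) - min(raw))
  pa <- diastolic + (systolic - diastolic) * w
  pd <- with_seed(seed, pa * (1 - gradient) +
                    if (noise_sd > 0) stats::rnorm(length(pa), 0, noise_sd)
                    else 0)
  pressure_tracing(time, pa, pd, pd_tol = max(2, 4 * noise_sd))
}

#' Generate a synthetic pressure-ratio pullback curve
#'
#' Value 1.0 at the proximal end with a single sigmoidal drop of magnitude
#' `drop` centered on the lesion; monotone non-increasing toward the distal
#' end.
#'
#' @param length pullback length, mm.
#' @param lesion_center lesion center position, mm (distal origin).
#' @param drop total ratio drop across the lesion, in \[0, 0.99).
#' @param width transition half-width, mm.
#' @param spacing sample spacing, mm.
#' @return an [ofr_pullback()].
#' @export
make_ofr_pullback <- function(length = 50, lesion_center = 25, drop = 0.15,
                              width = 2, spacing = 0.2) {
  if (drop < 0 || drop >= 0.99) stop("drop must be in [0, 0.99)")
  if (width <= 0) stop("width must be positive")
  x <- seq(0, length, by = spacing)
  v <- 1 - drop * stats::plogis((lesion_center - x) / width)
  ofr_pullback(x, pmin(v, 1))
}

#' Cohort specification for synthetic studies
#'
#' @param n_normal,n_diseased counts of plaque-free and lipid-bearing
#'   sections.
#' @param ranges named list of `c(min, max)` ranges overriding the default
#'   sampling ranges for [section_spec()] fields (`lumen_radius`,
#'   `wall_thickness_normal`, `wall_thickness_diseased`, `eccentricity`,
#'   `lipid_arc`, `cap_thickness`, `calcium_arc`).
#' @param seed integer seed.
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_normal = 2L, n_diseased = 3L, ranges = list(),
                        seed = 1L) {
  if (n_normal < 1L || n_diseased < 1L) stop("need at least one section per group")
  # default ranges echo clinical cross-section scales: reference lumen radii
  # ~1.1-1.5 mm with ~30% plaque burden; diseased lumina ~0.8-1.05 mm with
  # thick eccentric intima (~55-70% burden), caps 50-300 um
  def <- list(lumen_radius = c(1.1, 1.5),
              wall_thickness_normal = c(0.22, 0.32),
              wall_thickness_diseased = c(0.7, 1.0),
              eccentricity = c(0.3, 0.6),
              lipid_arc = c(70, 150),
              cap_thickness = c(50, 300),
              calcium_arc = c(0, 60))
  bad <- setdiff(names(ranges), names(def))
  if (length(bad)) stop("unknown range field(s): ", paste(bad, collapse = ", "))
  def[names(ranges)] <- ranges
  structure(list(n_normal = as.integer(n_normal),
                 n_diseased = as.integer(n_diseased),
                 ranges = def, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of labeled cross-sections
#'
#' Normal (plaque-free, thin concentric fibrous intima) sections are labeled
#' PR/DR; diseased (thick eccentric wall with a lipid crescent, optionally
#' calcium) sections are labeled PS/MLA/DS cyclically. Section parameters are
#' sampled uniformly within the cohort ranges; fully deterministic per seed.
#'
#' @param spec a [cohort_spec()].
#' @return list of entries `list(section = cross_section, label = chr,
#'   spec = section_spec)`.
#' @export
make_cohort <- function(spec) {
  ru <- function(rng) stats::runif(1, rng[1], rng[2])
  with_seed(spec$seed, {
    out <- list()
    norm_labels <- rep(c("PR", "DR"), length.out = spec$n_normal)
    dis_labels <- rep(c("MLA", "PS", "DS"), length.out = spec$n_diseased)
    for (i in seq_len(spec$n_normal)) {
      s <- section_spec(
        lumen_radius = ru(spec$ranges$lumen_radius),
        wall_thickness = ru(spec$ranges$wall_thickness_normal),
        eccentricity = 0, lipid_arc = 0, calcium_arc = 0,
        seed = stats::runif(1, 1, 2^30))
      out[[length(out) + 1L]] <- list(
        section = make_section(s, frame_id = i,
                               pullback_position = 30 + 2 * i),
        label = norm_labels[i], spec = s)
    }
    for (i in seq_len(spec$n_diseased)) {
      s <- section_spec(
        lumen_radius = ru(spec$ranges$lumen_radius) * 0.7,
        wall_thickness = ru(spec$ranges$wall_thickness_diseased),
        eccentricity = ru(spec$ranges$eccentricity),
        lipid_arc = ru(spec$ranges$lipid_arc),
        cap_thickness = ru(spec$ranges$cap_thickness),
        calcium_arc = local({
          # half the diseased sections carry calcium; arcs below 15 degrees
          # are not buildable as a region and mean "no calcium"
          ca <- if (stats::runif(1) < 0.5) ru(spec$ranges$calcium_arc) else 0
          if (ca < 15) 0 else ca
        }),
        seed = stats::runif(1, 1, 2^30))
      out[[length(out) + 1L]] <- list(
        section = make_section(s, frame_id = spec$n_normal + i,
                               pullback_position = 18 + 2 * i),
        label = dis_labels[i], spec = s)
    }
    out
  })
}
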