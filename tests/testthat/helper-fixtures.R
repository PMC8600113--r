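# shared fixtures and a cross-file cache for expensive finite-element solves

circle_contour <- function(r, n = 128L, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  contour(cbind(center[1] + r * cos(t), center[2] + r * sin(t)))
}

ellipse_contour <- function(a, b, n = 128L, angle = 0, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  contour(cbind(center[1] + x * cos(angle) - y * sin(angle),
                center[2] + x * sin(angle) + y * cos(angle)))
}

# uniform neo-Hookean material table (every tissue identical): G = 2 * mu
uniform_table <- function(mu) {
  m <- holzapfel(mu = mu, k1 = 0, k2 = 1, rho = 0)
  soft <- mooney_rivlin(mu / 2, mu / 2, 0, 0)
  list(lipid = soft, calcium = soft, fibrous = m, media = m, adventitia = m)
}

# annulus r in [1.5, 2.5]: IEL at 2.3 plus media 0.1 and adventitia 0.1;
# 720-gon circles so polygonal sagitta (~1e-5 relative) stays far below the
# stress tolerances checked against the axisymmetric closed forms
annulus_section <- function() {
  cross_section(1L, 10, circle_contour(1.5, 720L), circle_contour(2.3, 720L),
                list(), 0.1, 0.1)
}

.fe_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fe_cache)) {
    assign(name, force(expr), envir = .fe_cache)
  }
  get(name, envir = .fe_cache)
}

# Lame benchmark: uniform near-incompressible neo-Hookean annulus,
# internal pressure small enough for < 1% strain
lame_mu <- 50          # G = 100 kPa
lame_p <- 0.5          # kPa
lame_ri <- 1.5
lame_ro <- 2.5

lame_solution <- function() {
  cached("lame", {
    mesh <- generate_mesh(build_layered_geometry(annulus_section()))
    solve_cycle(mesh, uniform_table(lame_mu), lame_p, n_steps = 1L)
  })
}

lame_hoop <- function(r, p = lame_p, ri = lame_ri, ro = lame_ro)
  p * ri^2 / (ro^2 - ri^2) * (1 + ro^2 / r^2)
lame_radial <- function(r, p = lame_p, ri = lame_ri, ro = lame_ro)
  p * ri^2 / (ro^2 - ri^2) * (1 - ro^2 / r^2)

# hoop/radial stress of a solution step resolved about the origin
polar_stress <- function(mesh, step) {
  cen <- element_centroids_of(mesh)
  rr <- sqrt(rowSums(cen^2))
  a1 <- -cen[, 2] / rr; a2 <- cen[, 1] / rr
  list(r = rr,
       hoop = a1^2 * step$s11 + 2 * a1 * a2 * step$s12 + a2^2 * step$s22,
       radial = a2^2 * step$s11 - 2 * a1 * a2 * step$s12 + a1^2 * step$s22)
}

element_centroids_of <- function(mesh) {
  cbind((mesh$nodes[mesh$tri[, 1], 1] + mesh$nodes[mesh$tri[, 2], 1] +
           mesh$nodes[mesh$tri[, 3], 1]) / 3,
        (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
           mesh$nodes[mesh$tri[, 3], 2]) / 3)
}

# small diseased section solved once and reused (metrics, pipeline checks)
small_fibroatheroma_spec <- function(cap = 150)
  section_spec(lumen_radius = 0.9, wall_thickness = 0.65, eccentricity = 0.4,
               lipid_arc = 110, cap_thickness = cap, seed = 11)

small_study_cohort <- function(seed = 7L)
  cohort_spec(n_normal = 1L, n_diseased = 1L,
              ranges = list(lumen_radius = c(0.85, 0.95),
                            wall_thickness_normal = c(0.25, 0.3),
                            wall_thickness_diseased = c(0.55, 0.65),
                            lipid_arc = c(90, 110),
                            cap_thickness = c(120, 180),
                            calcium_arc = c(0, 0)),
              seed = seed)

# two runs of the same tiny study in fixed directories (shared with the
# determinism acceptance check)
tiny_study_runs <- function() {
  cached("tiny_runs", {
    base <- file.path(tempdir(), "pss_tiny_study")
    study <- file.path(base, "study")
    cfg_path <- write_synthetic_study(study, small_study_cohort(), seed = 7L)
    out <- lapply(c("run1", "run2"), function(tag) {
      cfg0 <- read_run_config(cfg_path)
      cfg <- run_config(sections = cfg0$sections, labels = cfg0$labels,
                        tracing = cfg0$tracing, pullback = cfg0$pullback,
                        output_dir = file.path(base, tag),
                        n_steps = 2L, write_vtk = TRUE, seed = 7L)
      run_lesion(cfg)
    })
    list(base = base, study = study,
         run1 = out[[1]], run2 = out[[2]],
         csv1 = file.path(base, "run1", "results.csv"),
         csv2 = file.path(base, "run2", "results.csv"))
  })
}
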