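test_that("von Mises stress matches its closed forms", {
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  s <- matrix(0, 3, 3); s[1, 1] <- -13.5
  expect_equal(von_mises(s), 13.5)
  tau <- 4.2
  sh <- matrix(0, 3, 3); sh[1, 2] <- sh[2, 1] <- tau
  expect_equal(von_mises(sh), sqrt(3) * tau)
  bad <- matrix(0, 3, 3); bad[1, 2] <- 1; bad[2, 1] <- 1.01
  expect_error(von_mises(bad), "symmetric")
})

fabricate_step <- function(load, vm, lumen) {
  list(load = load, von_mises = vm, deformed_lumen = lumen)
}

test_that("dPSS picks the superficial maximum at peak load", {
  # a real solved cycle: location sits on the superficial band
  sol <- lame_solution()
  d <- compute_dpss(sol)
  expect_true(d$element %in% sol$mesh$superficial)
  expect_lt(sqrt(sum(d$location^2)) - 1.5, 0.050)
  expect_equal(d$peak_load, lame_p)
  # analytic value: von Mises of the Lame state at the inner surface, 3%
  # (band-averaging tolerance: the band max sits at the innermost elements)
  G <- 2 * lame_mu; kap <- 1000 * G
  nu <- (3 * kap - 2 * G) / (2 * (3 * kap + G))
  szz <- nu * (lame_hoop(lame_ri) + lame_radial(lame_ri))
  vm_th <- plaquestress:::von_mises_components(lame_hoop(lame_ri),
                                               lame_radial(lame_ri), szz, 0)
  expect_equal(d$dpss, vm_th, tolerance = 0.03)
  # uniform fabricated field: dPSS equals the constant
  fake <- list(steps = list(fabricate_step(0, rep(0, 10), NULL),
                            fabricate_step(2, rep(30, 10), NULL)),
               mesh = sol$mesh)
  class(fake) <- "pss_solution"
  fake$mesh$superficial <- 1:10
  expect_equal(compute_dpss(fake)$dpss, 30)
  # zero-load cycle
  z <- solve_cycle(sol$mesh, uniform_table(lame_mu), 0)
  expect_equal(compute_dpss(z)$dpss, 0)
})

test_that("lumen diameter change uses area-equivalent diameters", {
  c1 <- circle_contour(1.00, 512L)
  c2 <- circle_contour(1.04, 512L)
  steps <- list(fabricate_step(0, NULL, c1), fabricate_step(1, NULL, c2))
  ld <- compute_ldc(steps)
  expect_equal(ld$ldc, 0.08, tolerance = 1e-3)
  expect_equal(ld$ldc_percent, 4.0, tolerance = 1e-2)
  same <- compute_ldc(list(fabricate_step(0, NULL, c1),
                           fabricate_step(1, NULL, c1)))
  expect_equal(same$ldc, 0)
  expect_equal(same$ldc_percent, 0)
  # elliptical deformation: effective diameter from the shoelace area
  el <- ellipse_contour(1.1, 0.95, 512L)
  lde <- compute_ldc(list(fabricate_step(0, NULL, c1),
                          fabricate_step(1, NULL, el)))
  d_el <- 2 * sqrt(polygon_area(el) / pi)
  expect_equal(lde$ldc, d_el - 2 * sqrt(polygon_area(c1) / pi),
               tolerance = 1e-6)
  expect_error(compute_ldc(list(fabricate_step(0, NULL, c1))), "two steps")
})

test_that("dPSS grows with peak load and LDC% is scale invariant", {
  # load ladder on a cached small section: elastic response is monotone
  sp <- section_spec(lumen_radius = 0.8, wall_thickness = 0.45,
                     eccentricity = 0.3, lipid_arc = 80, cap_thickness = 200,
                     media_thickness = 0.15, adventitia_thickness = 0.15,
                     seed = 31)
  mesh <- generate_mesh(build_layered_geometry(make_section(sp, n_vertices = 128L)))
  sol <- solve_cycle(mesh, default_materials(), 5, n_steps = 5L)
  vm_by_load <- vapply(sol$steps, function(s)
    max(s$von_mises[mesh$superficial]), 0)
  expect_true(all(diff(vm_by_load) > 0))
  # LDC% of the geometrically scaled section matches in the linear limit;
  # mesh sizes are scaled with the geometry so both meshes resolve the
  # section equally (same relative resolution)
  sc <- 1.5
  mesh1 <- generate_mesh(build_layered_geometry(make_section(sp, n_vertices = 128L)),
                         h_superficial = 0.045 / sc, h_bulk = 0.15 / sc)
  ld1 <- compute_ldc(solve_cycle(mesh1, uniform_table(30), 0.2, n_steps = 1L))
  cs2 <- make_section(section_spec(lumen_radius = 0.8 * sc,
                                   wall_thickness = 0.45 * sc,
                                   eccentricity = 0.3, lipid_arc = 80,
                                   cap_thickness = 200 * sc,
                                   media_thickness = 0.15 * sc,
                                   adventitia_thickness = 0.15 * sc,
                                   seed = 31), n_vertices = 128L)
  mesh2 <- generate_mesh(build_layered_geometry(cs2))
  ld2 <- compute_ldc(solve_cycle(mesh2, uniform_table(30), 0.2, n_steps = 1L))
  expect_equal(ld2$ldc_percent, ld1$ldc_percent, tolerance = 0.02)
})

test_that("stress metrics bundle the per-frame quantities", {
  sp <- small_fibroatheroma_spec()
  cs <- make_section(sp)
  sol <- cached("small_fa_solution", {
    solve_cycle(generate_mesh(build_layered_geometry(cs)),
                default_materials(), 4, n_steps = 1L)
  })
  sm <- stress_metrics(sol, cs, "MLA")
  expect_s3_class(sm, "stress_metrics")
  expect_equal(sm$cap_thickness, 150, tolerance = 0.05)
  expect_gt(sm$dpss, 0)
  expect_gt(sm$ldc_percent, 0)
  expect_equal(sm$peak_load, 4)
  df <- as.data.frame(sm)
  expect_named(df, c("frame_id", "position_label", "dpss_kpa", "ldc_mm",
                     "ldc_percent", "plaque_burden_pct", "cap_thickness_um",
                     "peak_load_kpa"))
})
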