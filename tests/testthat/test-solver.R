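test_that("zero load produces the stress-free reference state", {
  mesh <- cached("annulus_mesh", {
    generate_mesh(build_layered_geometry(annulus_section()))
  })
  sol <- solve_cycle(mesh, uniform_table(lame_mu), 0, n_steps = 1L)
  expect_length(sol$steps, 1L)
  st <- sol$steps[[1]]
  expect_identical(max(abs(st$u)), 0)
  expect_identical(max(st$von_mises), 0)
  expect_equal(st$J, rep(1, nrow(mesh$tri)))
})

test_that("rigid-body constraints remove exactly the three in-plane modes", {
  set.seed(12)
  nodes <- cbind(runif(40, -2, 2), runif(40, -2, 2))
  nodes <- sweep(nodes, 2, colMeans(nodes))
  C <- rigid_body_constraints(nodes)
  expect_equal(dim(C), c(3L, 80L))
  # each rigid mode is seen by exactly its constraint row
  tx <- rep(c(1, 0), 40); ty <- rep(c(0, 1), 40)
  rot <- as.vector(t(cbind(-nodes[, 2], nodes[, 1])))
  modes <- cbind(tx, ty, rot)
  M <- as.matrix(C %*% modes)
  expect_true(all(abs(diag(M)) > 1))    # each mode detected
  expect_equal(qr(M)$rank, 3L)          # and jointly independent
  # a centered radial (deformational) field is untouched by the constraints
  radial <- as.vector(t(nodes * 0.01))
  expect_lt(max(abs(as.numeric(C %*% radial))), 1e-12)
})

test_that("the converged solution is in equilibrium with tiny drift", {
  sol <- lame_solution()
  # residual norms recorded at convergence are below the stated tolerance
  expect_true(all(sol$residuals <= pmax(1e-8 * sol$load_norms, 1e-10)))
  # axisymmetric problem: no net translation or rotation
  st <- sol$steps[[2]]
  expect_lt(max(abs(colMeans(st$u))), 1e-9)
  mom <- sum(sol$mesh$nodes[, 1] * st$u[, 2] - sol$mesh$nodes[, 2] * st$u[, 1])
  expect_lt(abs(mom), 1e-8)
})

test_that("the annulus under small pressure matches the Lame solution", {
  sol <- lame_solution()
  mesh <- sol$mesh
  st <- sol$steps[[2]]
  ps <- polar_stress(mesh, st)
  sup <- mesh$superficial
  rm <- mean(ps$r[sup])
  expect_equal(mean(ps$hoop[sup]), lame_hoop(rm), tolerance = 0.02)
  expect_equal(mean(ps$radial[sup]), lame_radial(rm), tolerance = 0.05)
  # angular symmetry: coefficient of variation below 1% on each radius
  # (elements are grouped by centroid radius; the band spans several rows
  # whose radial stress gradient is not asymmetry)
  grp <- split(ps$hoop[sup], round(ps$r[sup], 3))
  grp <- grp[vapply(grp, length, 1L) >= 100L]
  expect_gt(length(grp), 0L)
  for (g in grp) expect_lt(stats::sd(g) / mean(g), 0.01)
  # displacement against the compressible closed form
  G <- 2 * lame_mu
  kap <- 1000 * G
  nu <- (3 * kap - 2 * G) / (2 * (3 * kap + G))
  Em <- 2 * G * (1 + nu)
  A <- lame_p * lame_ri^2 / (lame_ro^2 - lame_ri^2)
  u_ri <- (1 + nu) / Em * lame_ri * (A * (1 - 2 * nu) + A * lame_ro^2 / lame_ri^2)
  ur <- sqrt(rowSums(st$u[mesh$lumen_loop, ]^2))
  expect_equal(mean(ur), u_ri, tolerance = 0.03)
})

test_that("response is linear for small loads", {
  sol <- lame_solution()
  mesh <- sol$mesh
  half <- cached("lame_half", {
    solve_cycle(mesh, uniform_table(lame_mu), lame_p / 2, n_steps = 1L)
  })
  vm1 <- max(sol$steps[[2]]$von_mises[mesh$superficial])
  vm2 <- max(half$steps[[2]]$von_mises[mesh$superficial])
  expect_equal(vm1 / vm2, 2, tolerance = 0.01)
})

test_that("rotating the whole geometry rotates the solution with it", {
  sp <- section_spec(lumen_radius = 0.8, wall_thickness = 0.45,
                     eccentricity = 0.4, lipid_arc = 90, cap_thickness = 180,
                     media_thickness = 0.15, adventitia_thickness = 0.15,
                     seed = 21)
  cs <- make_section(sp, n_vertices = 128L)
  rot <- pi / 6
  Q <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  rot_contour <- function(cc) contour(unclass(cc) %*% t(Q), check = FALSE)
  cs_rot <- cross_section(cs$frame_id, cs$pullback_position,
                          rot_contour(cs$lumen), rot_contour(cs$iel),
                          lapply(cs$regions, function(r)
                            plaque_region(r$label, rot_contour(r$boundary))),
                          cs$media_thickness, cs$adventitia_thickness)
  tbl <- default_materials()
  s1 <- solve_cycle(generate_mesh(build_layered_geometry(cs)), tbl, 3,
                    n_steps = 1L)
  s2 <- solve_cycle(generate_mesh(build_layered_geometry(cs_rot)), tbl, 3,
                    n_steps = 1L)
  d1 <- compute_dpss(s1)
  d2 <- compute_dpss(s2)
  expect_equal(d2$dpss, d1$dpss, tolerance = 5e-3)
  # the critical location rotates with the section
  loc1_rot <- as.numeric(Q %*% d1$location)
  expect_equal(atan2(d2$location[2], d2$location[1]),
               atan2(loc1_rot[2], loc1_rot[1]), tolerance = 0.1)
})

test_that("dead and follower loads agree in the small-strain limit", {
  mesh <- cached("annulus_mesh", {
    generate_mesh(build_layered_geometry(annulus_section()))
  })
  dead <- solve_cycle(mesh, uniform_table(lame_mu), lame_p, n_steps = 1L,
                      control = solver_control(follower_load = FALSE))
  fol <- lame_solution()
  vm_d <- max(dead$steps[[2]]$von_mises[mesh$superficial])
  vm_f <- max(fol$steps[[2]]$von_mises[mesh$superficial])
  expect_equal(vm_d, vm_f, tolerance = 0.01)
})
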