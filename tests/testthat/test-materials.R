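random_state <- function(scale = 0.15, a = NULL) {
  repeat {
    F <- diag(2) + matrix(rnorm(4, 0, scale), 2, 2)
    if (det(F) > 0.4) break
  }
  if (is.null(a)) {
    a <- rnorm(2); a <- a / sqrt(sum(a^2))
  }
  kinematic_state(F, a = a)
}

sample_materials <- list(
  lipid_like = mooney_rivlin(2, 0, 2, 1.5),
  two_term = mooney_rivlin(10, 5, 0, 0),
  stiff_mr = mooney_rivlin(368, 0, 144, 2),
  neo_hookean = holzapfel(mu = 50, k1 = 0, k2 = 1, rho = 0),
  fibrous_like = holzapfel(mu = 14, k1 = 80, k2 = 20, rho = 0.85),
  pure_fiber = holzapfel(mu = 5, k1 = 40, k2 = 5, rho = 1))

energy_of <- function(state, m) {
  if (inherits(m, "mooney_rivlin")) mooney_rivlin_energy(state, m)
  else holzapfel_energy(state, m)
}

test_that("strain energies vanish in the reference state and obey stated limits", {
  id <- kinematic_state(diag(2))
  for (m in sample_materials) expect_identical(energy_of(id, m), 0)
  set.seed(1)
  # d1 = 0 reduces to the two-term Mooney-Rivlin polynomial
  m2 <- mooney_rivlin(7, 3, 0, 0)
  for (k in 1:20) {
    st <- random_state()
    iv <- plaquestress:::.iso_invariants(st)
    expect_equal(mooney_rivlin_energy(st, m2),
                 7 * (iv$I1b - 3) + 3 * (iv$I2b - 3), tolerance = 1e-12)
  }
  # rho = 0 makes the Holzapfel energy independent of the fiber direction
  mh <- holzapfel(mu = 10, k1 = 30, k2 = 4, rho = 0)
  for (k in 1:20) {
    F <- random_state()$F
    e1 <- holzapfel_energy(kinematic_state(F, a = c(1, 0)), mh)
    e2 <- holzapfel_energy(kinematic_state(F, a = c(0.6, 0.8)), mh)
    expect_equal(e1, e2, tolerance = 1e-12)
  }
  # rho = 0, k1 -> 0 degenerates to neo-Hookean mu(I1 - 3)
  mnh <- holzapfel(mu = 25, k1 = 1e-9, k2 = 1, rho = 0)
  st <- random_state()
  iv <- plaquestress:::.iso_invariants(st)
  expect_equal(holzapfel_energy(st, mnh), 25 * (iv$I1b - 3), tolerance = 1e-7)
})

test_that("closed-form energies at prescribed stretches are reproduced", {
  # isochoric plane-strain stretch: F = diag(l, 1/l), J = 1
  l <- 1.2
  st <- kinematic_state(diag(c(l, 1 / l)), a = c(0, 1))
  I1 <- l^2 + l^-2 + 1
  I2 <- 1 + l^2 + l^-2     # equals I1 for this F
  m <- mooney_rivlin(3.3, 1.1, 0.7, 2.0)
  expect_equal(mooney_rivlin_energy(st, m),
               3.3 * (I1 - 3) + 1.1 * (I2 - 3) + 0.7 * (exp(2 * (I1 - 3)) - 1),
               tolerance = 1e-10)
  # fiber stretch 1.1 along a, transverse 1/1.1
  lf <- 1.1
  stf <- kinematic_state(diag(c(1 / lf, lf)), a = c(0, 1))
  mh <- holzapfel(mu = 4, k1 = 12, k2 = 3, rho = 0.7)
  I1f <- lf^2 + lf^-2 + 1
  I4f <- lf^2
  q <- 3 * ((1 - 0.7) * (I1f - 3)^2 + 0.7 * (I4f - 1)^2)
  expect_equal(holzapfel_energy(stf, mh), 4 * (I1f - 3) + 12 / 3 * (exp(q) - 1),
               tolerance = 1e-10)
})

test_that("energies are objective and the fiber switch is tension-only", {
  set.seed(2)
  for (k in 1:15) {
    F <- random_state(0.2)$F
    th <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    for (m in sample_materials[c("two_term", "fibrous_like")]) {
      e0 <- energy_of(kinematic_state(F, a = c(0, 1)), m)
      eq <- energy_of(kinematic_state(Q %*% F, a = c(0, 1)), m)
      expect_equal(eq, e0, tolerance = 1e-10)
    }
  }
  # fiber compression carries no fiber energy under the tension-only switch
  mh <- holzapfel(mu = 1e-9, k1 = 10, k2 = 2, rho = 1, tension_only = TRUE)
  comp <- kinematic_state(diag(c(1 / 0.9, 0.9)), a = c(0, 1))  # I4 < 1
  expect_lt(holzapfel_energy(comp, mh), 1e-6)
  mh2 <- holzapfel(mu = 1e-9, k1 = 10, k2 = 2, rho = 1, tension_only = FALSE)
  expect_gt(holzapfel_energy(comp, mh2), 1e-3)
})

test_that("Cauchy stress is exact at identity and consistent near identity", {
  pen <- volumetric_penalty(1e4)
  id <- kinematic_state(diag(2))
  for (m in sample_materials) {
    s <- cauchy_stress(id, m, pen)
    expect_identical(max(abs(s)), 0)
  }
  set.seed(4)
  for (k in 1:10) {
    eps <- 1e-5
    A <- matrix(rnorm(4), 2, 2)
    st <- kinematic_state(diag(2) + eps * A)
    s <- cauchy_stress(st, sample_materials$fibrous_like, pen)
    expect_lt(max(abs(s - t(s))), 1e-12 * max(1, max(abs(s))))
    expect_lt(max(abs(s)), 1e4 * 10 * eps)   # O(eps) with kappa the stiffest scale
  }
})

test_that("stress equals the finite-difference derivative of the energy", {
  # first Piola-Kirchhoff from the Cauchy stress vs central differences of
  # the total (isochoric + volumetric) energy, 100 random states per material
  set.seed(6)
  pen <- volumetric_penalty(5e3)
  total_energy <- function(F, m, a) {
    st <- kinematic_state(F, a = a)
    energy_of(st, m) + pen$kappa / 2 * (st$J - 1)^2
  }
  for (m in sample_materials) {
    for (k in 1:100) {
      a <- rnorm(2); a <- a / sqrt(sum(a^2))
      st <- random_state(0.08, a = a)
      sig <- cauchy_stress(st, m, pen)
      # P = J sigma F^{-T} (in-plane block)
      Finv <- solve(st$F)
      P <- st$J * sig[1:2, 1:2] %*% t(Finv)
      h <- 1e-6
      Pfd <- matrix(0, 2, 2)
      for (i in 1:2) for (j in 1:2) {
        Fp <- st$F; Fm <- st$F
        Fp[i, j] <- Fp[i, j] + h
        Fm[i, j] <- Fm[i, j] - h
        Pfd[i, j] <- (total_energy(Fp, m, a) - total_energy(Fm, m, a)) / (2 * h)
      }
      expect_equal(P, Pfd, tolerance = 1e-6)
    }
  }
})

test_that("tissue labels map to their constitutive models", {
  tbl <- default_materials()
  expect_s3_class(material_for_region("lipid", tbl), "mooney_rivlin")
  expect_s3_class(material_for_region("calcium", tbl), "mooney_rivlin")
  for (lab in c("fibrous", "media", "adventitia"))
    expect_s3_class(material_for_region(lab, tbl), "holzapfel")
  expect_error(material_for_region("thrombus", tbl), "thrombus")
  # a config missing a label is reported by name
  expect_error(material_for_region("media", tbl[c("lipid", "fibrous")]),
               "media")
  # overflow guard names the exponent
  big <- kinematic_state(diag(c(40, 1 / 40)))
  expect_error(mooney_rivlin_energy(big, mooney_rivlin(1, 0, 1, 2)),
               "overflow")
})
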