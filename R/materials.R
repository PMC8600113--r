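#' Mooney-Rivlin material parameters
#'
#' Exponential three-term Mooney-Rivlin strain energy for isotropic plaque
#' components (lipid pool, calcification):
#' \deqn{W = c_1(\bar I_1 - 3) + c_2(\bar I_2 - 3) + d_1(e^{d_2(\bar I_1 - 3)} - 1)}
#' evaluated on the isochoric invariants, plus a volumetric penalty handled by
#' the solver (see [volumetric_penalty()]).
#'
#' @param c1,c2,d1 material constants in kPa.
#' @param d2 dimensionless exponential coefficient.
#' @return object of class `"mooney_rivlin"`.
#' @export
mooney_rivlin <- function(c1, c2 = 0, d1 = 0, d2 = 0) {
  p <- list(c1 = c1, c2 = c2, d1 = d1, d2 = d2)
  if (!all(vapply(p, is.finite, TRUE))) stop("Mooney-Rivlin parameters must be finite")
  if (c1 + c2 <= 0 && d1 * d2 <= 0) stop("Mooney-Rivlin material has no stiffness")
  structure(p, class = "mooney_rivlin")
}

#' Holzapfel-type anisotropic material parameters
#'
#' Two-term fiber-reinforced strain energy for arterial tissue (intimal
#' fibrous tissue, media, adventitia):
#' \deqn{W = \mu(\bar I_1 - 3) + \frac{k_1}{k_2}\left(
#'   e^{k_2[(1-\rho)(\bar I_1-3)^2 + \rho(\bar I_4-1)^2]} - 1\right)}
#' with a single in-plane circumferential fiber family; \eqn{\bar I_4} is the
#' squared fiber stretch. The fiber term is active only in fiber tension
#' (\eqn{\bar I_4 \ge 1}) unless `tension_only = FALSE`.
#'
#' @param mu,k1 material constants in kPa.
#' @param k2 dimensionless exponential coefficient, must be > 0 when k1 > 0.
#' @param rho dimensionless anisotropy weight in \[0, 1\]; 0 gives an isotropic
#'   exponential, 1 a pure fiber term.
#' @param tension_only logical; clamp the fiber term for I4 < 1 (default TRUE).
#' @return object of class `"holzapfel"`.
#' @export
holzapfel <- function(mu, k1 = 0, k2 = 1, rho = 0, tension_only = TRUE) {
  if (!all(is.finite(c(mu, k1, k2, rho)))) stop("Holzapfel parameters must be finite")
  if (mu <= 0) stop("Holzapfel mu must be positive")
  if (k2 <= 0) stop("Holzapfel k2 must be positive")
  if (k1 < 0) stop("Holzapfel k1 must be non-negative")
  if (rho < 0 || rho > 1) stop("Holzapfel rho must be in [0, 1]")
  structure(list(mu = mu, k1 = k1, k2 = k2, rho = rho,
                 tension_only = isTRUE(tension_only)),
            class = "holzapfel")
}

#' Volumetric penalty for near-incompressibility
#'
#' The solver enforces near-incompressibility with the penalty energy
#' \eqn{W_{vol} = \kappa (J-1)^2 / 2}, replacing a mixed (hybrid)
#' displacement-pressure formulation. `kappa` should dominate the material's
#' shear scale (>= 100x) for the response to be effectively isochoric.
#'
#' @param kappa bulk-like penalty modulus in kPa.
#' @return object of class `"volumetric_penalty"`.
#' @export
volumetric_penalty <- function(kappa) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be positive")
  structure(list(kappa = kappa), class = "volumetric_penalty")
}

# Leading small-strain shear modulus of a material (used to scale kappa).
shear_scale <- function(material) {
  if (inherits(material, "mooney_rivlin"))
    2 * (material$c1 + material$c2 + material$d1 * material$d2)
  else if (inherits(material, "holzapfel"))
    2 * material$mu
  else stop("unknown material class")
}

#' Plane-strain kinematic state
#'
#' Wraps a 2x2 in-plane deformation gradient under the plane-strain assumption
#' (out-of-plane stretch 1) and exposes the derived quantities used by the
#' strain-energy functions: J, the right Cauchy-Green tensor and the
#' invariants I1, I2, I4 (I4 for reference fiber direction `a`).
#'
#' @param F 2x2 in-plane deformation gradient.
#' @param a reference fiber direction, in-plane unit vector
#'   (default circumferential placeholder `c(0, 1)`).
#' @return object of class `"kinematic_state"` with elements `F`, `J`, `C`
#'   (3x3), `I1`, `I2`, `I4`, `a`.
#' @export
kinematic_state <- function(F, a = c(0, 1)) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(2L, 2L))) stop("F must be 2x2 (plane strain)")
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (!is.finite(J) || J <= 0) stop("det(F) must be positive, got ", format(J))
  a <- a / sqrt(sum(a^2))
  C2 <- t(F) %*% F
  C <- rbind(cbind(C2, c(0, 0)), c(0, 0, 1))
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I4 <- drop(t(a) %*% C2 %*% a)
  structure(list(F = F, J = J, C = C, I1 = I1, I2 = I2, I4 = I4, a = a),
            class = "kinematic_state")
}

# Isochoric invariants of a kinematic state (plane strain, lambda_z = 1).
.iso_invariants <- function(state) {
  J <- state$J
  list(I1b = J^(-2 / 3) * state$I1,
       I2b = J^(-4 / 3) * state$I2,
       I4b = J^(-2 / 3) * state$I4)
}

#' Mooney-Rivlin strain energy density
#'
#' @param state a [kinematic_state()].
#' @param p a [mooney_rivlin()] parameter set.
#' @return isochoric strain energy density in kPa.
#' @export
mooney_rivlin_energy <- function(state, p) {
  iv <- .iso_invariants(state)
  ex <- p$d2 * (iv$I1b - 3)
  if (ex > 50) stop("overflow in Mooney-Rivlin exponential: d2*(I1-3) = ", format(ex))
  p$c1 * (iv$I1b - 3) + p$c2 * (iv$I2b - 3) + p$d1 * (expm1(ex))
}

#' Holzapfel strain energy density
#'
#' @param state a [kinematic_state()]; the fiber direction is taken from the
#'   state (`state$a`).
#' @param p a [holzapfel()] parameter set.
#' @return isochoric strain energy density in kPa.
#' @export
holzapfel_energy <- function(state, p) {
  iv <- .iso_invariants(state)
  e1 <- iv$I1b - 3
  e4 <- iv$I4b - 1
  if (p$tension_only) e4 <- max(e4, 0)
  q <- p$k2 * ((1 - p$rho) * e1^2 + p$rho * e4^2)
  if (q > 50) stop("overflow in Holzapfel exponential: k2*Q = ", format(q))
  p$mu * e1 + p$k1 / p$k2 * expm1(q)
}

#' Cauchy stress for a plane-strain hyperelastic state
#'
#' Computes the full 3x3 Cauchy stress
#' \eqn{\sigma = \frac{2}{J} F \frac{\partial W_{iso}}{\partial C} F^T
#'   + \kappa(J-1) I}, including the out-of-plane component
#' \eqn{\sigma_{zz}} generated by the plane-strain constraint.
#'
#' @param state a [kinematic_state()].
#' @param material a [mooney_rivlin()] or [holzapfel()] material.
#' @param penalty a [volumetric_penalty()].
#' @return 3x3 symmetric Cauchy stress in kPa.
#' @export
cauchy_stress <- function(state, material, penalty) {
  mp <- .material_columns(material, n = 1L, kappa = penalty$kappa,
                          a1 = state$a[1], a2 = state$a[2])
  F <- state$F
  r <- .element_response(F[1, 1], F[1, 2], F[2, 1], F[2, 2], mp,
                         want_cauchy = TRUE)
  s <- matrix(c(r$s11, r$s12, 0,
                r$s12, r$s22, 0,
                0, 0, r$s33), 3, 3)
  s
}

# ---- vectorized material kernel -------------------------------------------
#
# All element-level mechanics go through .element_response(): given per-element
# 2x2 deformation-gradient components and per-element material columns, return
# energy density, first Piola-Kirchhoff stress and (optionally) Cauchy stress.
# Everything is vectorized over elements.

# Build per-element parameter columns. `material` may be a single material or
# a list of materials indexed by `index` (length n).
.material_columns <- function(material, n, kappa, a1, a2, index = NULL) {
  zero <- numeric(n)
  mp <- list(model = integer(n), c1 = zero, c2 = zero, d1 = zero, d2 = zero,
             mu = zero, k1 = zero, k2 = rep(1, n), rho = zero,
             tension_only = rep(TRUE, n),
             kappa = rep_len(kappa, n), a1 = rep_len(a1, n), a2 = rep_len(a2, n))
  fill <- function(idx, m) {
    if (inherits(m, "mooney_rivlin")) {
      mp$model[idx] <<- 1L
      mp$c1[idx] <<- m$c1; mp$c2[idx] <<- m$c2
      mp$d1[idx] <<- m$d1; mp$d2[idx] <<- m$d2
    } else if (inherits(m, "holzapfel")) {
      mp$model[idx] <<- 2L
      mp$mu[idx] <<- m$mu; mp$k1[idx] <<- m$k1; mp$k2[idx] <<- m$k2
      mp$rho[idx] <<- m$rho; mp$tension_only[idx] <<- m$tension_only
    } else stop("unknown material class")
  }
  if (is.null(index)) fill(seq_len(n), material)
  else for (k in seq_along(material)) {
    idx <- which(index == k)
    if (length(idx)) fill(idx, material[[k]])
  }
  mp
}

.element_response <- function(F11, F12, F21, F22, mp, want_cauchy = FALSE) {
  J <- F11 * F22 - F12 * F21
  if (any(!is.finite(J)) || any(J <= 0))
    stop("non-positive Jacobian in deformation state")
  C11 <- F11^2 + F21^2
  C22 <- F12^2 + F22^2
  C12 <- F11 * F12 + F21 * F22
  I1 <- C11 + C22 + 1
  trC2 <- C11^2 + 2 * C12^2 + C22^2 + 1
  I2 <- (I1^2 - trC2) / 2
  J2 <- J * J
  Ci11 <- C22 / J2; Ci22 <- C11 / J2; Ci12 <- -C12 / J2
  a1 <- mp$a1; a2 <- mp$a2
  I4 <- a1^2 * C11 + 2 * a1 * a2 * C12 + a2^2 * C22

  Jm23 <- J^(-2 / 3); Jm43 <- Jm23 * Jm23
  I1b <- Jm23 * I1; I2b <- Jm43 * I2; I4b <- Jm23 * I4
  e1 <- I1b - 3
  e4 <- I4b - 1
  e4 <- ifelse(mp$tension_only, pmax(e4, 0), e4)

  is_mr <- mp$model == 1L
  # energy and first derivatives wrt isochoric invariants
  ex_mr <- mp$d2 * e1
  q_h <- mp$k2 * ((1 - mp$rho) * e1^2 + mp$rho * e4^2)
  if (any(ifelse(is_mr, ex_mr, q_h) > 60))
    stop("overflow in material exponential (argument > 60)")
  W1 <- ifelse(is_mr,
               mp$c1 + mp$d1 * mp$d2 * exp(ex_mr),
               mp$mu + 2 * mp$k1 * (1 - mp$rho) * e1 * exp(q_h))
  W2 <- ifelse(is_mr, mp$c2, 0)
  W4 <- ifelse(is_mr, 0, 2 * mp$k1 * mp$rho * e4 * exp(q_h))
  Wiso <- ifelse(is_mr,
                 mp$c1 * e1 + mp$c2 * (I2b - 3) + mp$d1 * expm1(ex_mr),
                 mp$mu * e1 + mp$k1 / mp$k2 * expm1(q_h))
  kap <- mp$kappa
  W <- Wiso + kap / 2 * (J - 1)^2

  # S = 2 dW/dC (3x3 block diagonal), via chain rule on isochoric invariants
  # dI1b/dC = Jm23 (I - I1/3 Cinv); dI2b/dC = Jm43 (I1 I - C - 2 I2/3 Cinv)
  # dI4b/dC = Jm23 (a x a - I4/3 Cinv);  dJ/dC = J/2 Cinv
  g1 <- 2 * W1 * Jm23
  g2 <- 2 * W2 * Jm43
  g4 <- 2 * W4 * Jm23
  pv <- kap * (J - 1) * J       # volumetric: S_vol = pv * Cinv
  cc <- -(g1 * I1 / 3 + g2 * 2 * I2 / 3 + g4 * I4 / 3) + pv
  S11 <- g1 + g2 * (I1 - C11) + g4 * a1 * a1 + cc * Ci11
  S22 <- g1 + g2 * (I1 - C22) + g4 * a2 * a2 + cc * Ci22
  S12 <- g2 * (-C12) + g4 * a1 * a2 + cc * Ci12
  S33 <- g1 + g2 * (I1 - 1) + cc        # C33 = 1, Cinv33 = 1, (a x a)33 = 0

  P11 <- F11 * S11 + F12 * S12
  P12 <- F11 * S12 + F12 * S22
  P21 <- F21 * S11 + F22 * S12
  P22 <- F21 * S12 + F22 * S22

  out <- list(W = W, J = J,
              P11 = P11, P12 = P12, P21 = P21, P22 = P22)
  if (want_cauchy) {
    out$s11 <- (P11 * F11 + P12 * F12) / J
    out$s22 <- (P21 * F21 + P22 * F22) / J
    out$s12 <- (P11 * F21 + P12 * F22) / J
    out$s33 <- S33 / J
  }
  out
}

#' Assign a material model to a tissue label
#'
#' Realizes the tissue-to-model mapping: lipid and calcified plaque are
#' isotropic Mooney-Rivlin; intimal fibrous tissue, media and adventitia are
#' anisotropic Holzapfel-type with circumferential fibers.
#'
#' @param label one of `"lipid"`, `"calcium"`, `"fibrous"`, `"media"`,
#'   `"adventitia"`.
#' @param table a material table as returned by [default_materials()] or read
#'   from a YAML config by [read_materials()].
#' @return the material object ([mooney_rivlin()] or [holzapfel()]) for the label.
#' @export
material_for_region <- function(label, table = default_materials()) {
  known <- c("lipid", "calcium", "fibrous", "media", "adventitia")
  if (!label %in% known)
    stop("unknown tissue label '", label, "' (expected one of ",
         paste(known, collapse = ", "), ")")
  if (is.null(table[[label]]))
    stop("material table has no parameter set for label '", label, "'")
  m <- table[[label]]
  expected <- if (label %in% c("lipid", "calcium")) "mooney_rivlin" else "holzapfel"
  if (!inherits(m, expected))
    stop("label '", label, "' must use the ", expected, " model")
  m
}

#' Default material parameter table
#'
#' Reads the packaged parameter file `inst/extdata/materials.yaml`. The
#' constants are transcriptions of commonly used plaque and coronary-layer
#' values from the vascular biomechanics literature (see the file itself for
#' per-tissue source notes); they are defaults, not fitted values, and can be
#' replaced by any YAML file with the same layout via [read_materials()].
#'
#' @return named list of materials keyed by tissue label, with an attribute
#'   `"source"` carrying the file path.
#' @export
default_materials <- function() {
  read_materials(system.file("extdata", "materials.yaml",
                             package = "plaquestress", mustWork = TRUE))
}

#' Read a material parameter table from YAML
#'
#' @param path YAML file with one block per tissue label:
#'   `{model: mooney_rivlin|holzapfel, parameters: {...}, source: "..."}`.
#' @return named list of material objects keyed by label.
#' @export
read_materials <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(blk) {
    pars <- blk$parameters
    m <- switch(blk$model,
      mooney_rivlin = mooney_rivlin(pars$c1, pars$c2 %||% 0, pars$d1 %||% 0,
                                    pars$d2 %||% 0),
      holzapfel = holzapfel(pars$mu, pars$k1 %||% 0, pars$k2 %||% 1,
                            pars$rho %||% 0,
                            tension_only = pars$tension_only %||% TRUE),
      stop("unknown material model '", blk$model, "'"))
    attr(m, "source") <- blk$source %||% ""
    m
  })
  attr(out, "source") <- path
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
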