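#' Solver control settings
#'
#' @param rel_tol relative residual tolerance (vs applied load norm).
#' @param abs_tol absolute residual tolerance (force units).
#' @param max_iter maximum Newton iterations per load level.
#' @param max_bisect maximum levels of automatic load-step bisection after a
#'   Newton failure.
#' @param penalty_factor volumetric penalty stiffness as a multiple of each
#'   material's small-strain shear modulus (>= 100 for near-incompressibility).
#' @param follower_load if `TRUE` (default) the lumen pressure acts on the
#'   deformed boundary (follower load); `FALSE` gives a dead load (testing).
#' @param fd_step finite-difference step for the element tangent, mm.
#' @return list of class `"solver_control"`.
#' @export
solver_control <- function(rel_tol = 1e-8, abs_tol = 1e-10, max_iter = 40L,
                           max_bisect = 5L, penalty_factor = 1000,
                           follower_load = TRUE, fd_step = 1e-7) {
  if (penalty_factor < 100)
    stop("penalty_factor must be >= 100 (near-incompressibility)")
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_iter = as.integer(max_iter),
                 max_bisect = as.integer(max_bisect),
                 penalty_factor = penalty_factor,
                 follower_load = isTRUE(follower_load),
                 fd_step = fd_step),
            class = "solver_control")
}

#' Rigid-body constraint matrix
#'
#' Three Lagrange-multiplier constraints removing the in-plane rigid-body
#' modes over all nodes: zero mean translation (two rows) and zero net
#' rotation about the origin (one row, `sum(x_i u_yi - y_i u_xi) = 0`). This
#' restrains the rotational freedom (the model cannot roll) while leaving
#' radial deformation free.
#'
#' @param nodes N x 2 matrix of reference node coordinates.
#' @return a 3 x 2N sparse matrix (dof ordering `ux1, uy1, ux2, uy2, ...`).
#' @export
rigid_body_constraints <- function(nodes) {
  n <- nrow(nodes)
  ix <- 2 * seq_len(n) - 1L
  iy <- 2 * seq_len(n)
  Matrix::sparseMatrix(
    i = c(rep(1L, n), rep(2L, n), rep(3L, n), rep(3L, n)),
    j = c(ix, iy, ix, iy),
    x = c(rep(1, n), rep(1, n), -nodes[, 2], nodes[, 1]),
    dims = c(3L, 2L * n))
}

#' Augment an assembled system with rigid-body constraints
#'
#' Builds the saddle-point (KKT) system `[K Ct; C 0]` enforcing `C u = 0` by
#' Lagrange multipliers.
#'
#' @param K assembled tangent (2N x 2N sparse).
#' @param R residual vector (length 2N).
#' @param C constraint matrix from [rigid_body_constraints()].
#' @param u current displacement vector; `lambda` current multipliers.
#' @return list with the augmented matrix `A` and right-hand side `b` for the
#'   Newton update `A [du; dlambda] = b`.
#' @export
apply_rigid_body_constraints <- function(K, R, C, u, lambda = numeric(nrow(C))) {
  nc <- nrow(C)
  A <- rbind(cbind(K, Matrix::t(C)),
             cbind(C, Matrix::Matrix(0, nc, nc)))
  b <- c(-(R + as.numeric(Matrix::t(C) %*% lambda)), -as.numeric(C %*% u))
  list(A = A, b = b)
}

# ---- element precomputation ------------------------------------------------
#
# Near-incompressibility uses the average-nodal-pressure treatment for linear
# triangles: the volumetric energy is sum_n V_n kappa_n/2 (Jbar_n - 1)^2 with
# Jbar_n the reference-volume-weighted average Jacobian over the elements
# touching node n. This removes the volumetric locking and element-wise
# pressure checkerboard of a purely local penalty on constant-strain
# triangles, and plays the role of the mixed (hybrid) element formulation.
# The isochoric part of the tangent is assembled by element-local forward
# differences; the volumetric tangent is analytic (rank-one nodal term plus
# the det-Hessian geometric term).

# Precompute reference element data for constant-strain triangles, the
# per-element material columns and the assembly index patterns.
fe_setup <- function(mesh, materials, control) {
  tri <- mesh$tri
  nd <- mesh$nodes
  x1 <- nd[tri[, 1], 1]; y1 <- nd[tri[, 1], 2]
  x2 <- nd[tri[, 2], 1]; y2 <- nd[tri[, 2], 2]
  x3 <- nd[tri[, 3], 1]; y3 <- nd[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  A <- det / 2
  if (any(A <= 0)) stop("inverted reference element")
  B <- cbind((y2 - y3), (y3 - y1), (y1 - y2)) / det   # dN_i/dX
  Cc <- cbind((x3 - x2), (x1 - x3), (x2 - x1)) / det  # dN_i/dY
  labs <- sort(unique(mesh$region))
  mats <- lapply(labs, material_for_region, table = materials)
  index <- match(mesh$region, labs)
  kappa_each <- control$penalty_factor *
    vapply(mats, shear_scale, 0)[index]
  cen <- element_centroids(mesh)
  rr <- sqrt(rowSums(cen^2))
  a1 <- -cen[, 2] / rr; a2 <- cen[, 1] / rr   # circumferential fiber direction
  mp <- .material_columns(mats, n = nrow(tri), kappa = kappa_each,
                          a1 = a1, a2 = a2, index = index)
  ndof <- 2L * nrow(nd)
  edof <- cbind(2L * tri[, 1] - 1L, 2L * tri[, 2] - 1L, 2L * tri[, 3] - 1L,
                2L * tri[, 1],      2L * tri[, 2],      2L * tri[, 3])
  kI <- matrix(0L, nrow(tri), 36L)
  kJ <- matrix(0L, nrow(tri), 36L)
  for (i in 1:6) for (k in 1:6) {
    kI[, (k - 1L) * 6L + i] <- edof[, i]
    kJ[, (k - 1L) * 6L + i] <- edof[, k]
  }
  loop <- mesh$lumen_loop
  e_a <- loop
  e_b <- c(loop[-1L], loop[1L])
  # nodal volumes and nodal penalty moduli for the average-nodal-pressure
  # volumetric treatment (kappa stays a per-element material property and is
  # averaged onto the node patches)
  n_nodes <- nrow(nd)
  Vn <- accumulate_dof(rep(A / 3, 3L), as.vector(tri), n_nodes)
  kappa_n <- accumulate_dof(rep(A / 3, 3L) * rep(kappa_each, 3L),
                            as.vector(tri), n_nodes) / Vn
  mp0 <- mp
  mp0$kappa <- numeric(nrow(tri))
  list(A = A, B = B, C = Cc, mp = mp, mp0 = mp0, edof = edof, kI = kI, kJ = kJ,
       ndof = ndof, edge_a = e_a, edge_b = e_b,
       nodes = nd, tri = tri, Vn = Vn, kappa_n = kappa_n)
}

fe_deformation <- function(setup, Ue) {
  list(F11 = 1 + rowSums(Ue[, 1:3] * setup$B),
       F12 = rowSums(Ue[, 1:3] * setup$C),
       F21 = rowSums(Ue[, 4:6] * setup$B),
       F22 = 1 + rowSums(Ue[, 4:6] * setup$C))
}

# isochoric element internal nodal forces (M x 6) for displacement table Ue
fe_internal_iso <- function(setup, Ue, want_cauchy = FALSE) {
  Fc <- fe_deformation(setup, Ue)
  r <- .element_response(Fc$F11, Fc$F12, Fc$F21, Fc$F22, setup$mp0,
                         want_cauchy = want_cauchy)
  A <- setup$A
  fe <- cbind(A * (r$P11 * setup$B[, 1] + r$P12 * setup$C[, 1]),
              A * (r$P11 * setup$B[, 2] + r$P12 * setup$C[, 2]),
              A * (r$P11 * setup$B[, 3] + r$P12 * setup$C[, 3]),
              A * (r$P21 * setup$B[, 1] + r$P22 * setup$C[, 1]),
              A * (r$P21 * setup$B[, 2] + r$P22 * setup$C[, 2]),
              A * (r$P21 * setup$B[, 3] + r$P22 * setup$C[, 3]))
  list(fe = fe, response = r, Fc = Fc)
}

# dJ/du_e for every element: 6 columns (x dofs of nodes 1-3, then y dofs)
fe_det_gradient <- function(setup, Fc) {
  cbind(Fc$F22 * setup$B[, 1] - Fc$F21 * setup$C[, 1],
        Fc$F22 * setup$B[, 2] - Fc$F21 * setup$C[, 2],
        Fc$F22 * setup$B[, 3] - Fc$F21 * setup$C[, 3],
        -Fc$F12 * setup$B[, 1] + Fc$F11 * setup$C[, 1],
        -Fc$F12 * setup$B[, 2] + Fc$F11 * setup$C[, 2],
        -Fc$F12 * setup$B[, 3] + Fc$F11 * setup$C[, 3])
}

# full internal forces: isochoric + average-nodal-pressure volumetric part
fe_forces <- function(setup, Ue, want_cauchy = FALSE) {
  iso <- fe_internal_iso(setup, Ue, want_cauchy = want_cauchy)
  J <- iso$response$J
  gvec <- fe_det_gradient(setup, iso$Fc)
  n_nodes <- length(setup$Vn)
  Jbar_n <- accumulate_dof(rep(setup$A / 3, 3L) * rep(J, 3L),
                           as.vector(setup$tri), n_nodes) / setup$Vn
  p_n <- setup$kappa_n * (Jbar_n - 1)
  pbar <- (p_n[setup$tri[, 1]] + p_n[setup$tri[, 2]] + p_n[setup$tri[, 3]]) / 3
  fe <- iso$fe + (setup$A * pbar) * gvec
  out <- list(fe = fe, response = iso$response, Fc = iso$Fc, J = J,
              gvec = gvec, pbar = pbar, p_n = p_n, Jbar_n = Jbar_n)
  if (want_cauchy) {
    # reported stresses use a once-more patch-smoothed pressure: the raw
    # kappa*(Jbar - 1) field carries mesh-scale noise (kappa amplifies
    # Jacobian ripple ~1e-7) that one area-weighted node-patch average
    # removes; the equilibrium solve itself is untouched
    pn2 <- accumulate_dof(rep(setup$A / 3, 3L) * rep(pbar, 3L),
                          as.vector(setup$tri), n_nodes) / setup$Vn
    pbar_s <- (pn2[setup$tri[, 1]] + pn2[setup$tri[, 2]] +
                 pn2[setup$tri[, 3]]) / 3
    out$s11 <- iso$response$s11 + pbar_s
    out$s22 <- iso$response$s22 + pbar_s
    out$s33 <- iso$response$s33 + pbar_s
    out$s12 <- iso$response$s12
  }
  out
}

fe_gather <- function(setup, u) {
  tri <- setup$tri
  cbind(u[2L * tri[, 1] - 1L], u[2L * tri[, 2] - 1L], u[2L * tri[, 3] - 1L],
        u[2L * tri[, 1]],      u[2L * tri[, 2]],      u[2L * tri[, 3]])
}

fe_scatter <- function(setup, fe) {
  accumulate_dof(as.vector(fe), as.vector(setup$edof), setup$ndof)
}

# sum values into a dense vector by index (duplicates accumulate)
accumulate_dof <- function(vals, idx, n) {
  acc <- rowsum(vals, idx)
  out <- numeric(n)
  out[as.integer(rownames(acc))] <- acc
  out
}

# follower (or dead) pressure load on the lumen edges; returns global force
# vector and, when `tangent`, the load-stiffness triplets
fe_pressure <- function(setup, u, p, follower = TRUE, tangent = FALSE) {
  a <- setup$edge_a; b <- setup$edge_b
  xa <- setup$nodes[a, 1]; ya <- setup$nodes[a, 2]
  xb <- setup$nodes[b, 1]; yb <- setup$nodes[b, 2]
  if (follower) {
    xa <- xa + u[2L * a - 1L]; ya <- ya + u[2L * a]
    xb <- xb + u[2L * b - 1L]; yb <- yb + u[2L * b]
  }
  dx <- xb - xa; dy <- yb - ya
  # CCW lumen loop: (dy, -dx) points out of the lumen into the wall
  fx <- p * dy / 2; fy <- -p * dx / 2
  f <- accumulate_dof(c(fx, fy, fx, fy),
                      c(2L * a - 1L, 2L * a, 2L * b - 1L, 2L * b),
                      setup$ndof)
  out <- list(f = f)
  if (tangent && follower && p != 0) {
    ne <- length(a)
    half <- rep(p / 2, ne)
    # d f_ax / d ya = -p/2, d f_ax / d yb = +p/2 (same for node b rows)
    rows <- c(2L * a - 1L, 2L * a - 1L, 2L * b - 1L, 2L * b - 1L,
              2L * a,      2L * a,      2L * b,      2L * b)
    colsj <- c(2L * a, 2L * b, 2L * a, 2L * b,
               2L * a - 1L, 2L * b - 1L, 2L * a - 1L, 2L * b - 1L)
    vals <- c(-half, half, -half, half,
              half, -half, half, -half)
    out$tangent <- list(i = rows, j = colsj, x = vals)
  }
  out
}

# assemble the global tangent: element-local central differences of the
# isochoric forces (at the tension-only fiber switch this yields the
# symmetric generalized Jacobian, the correct semismooth-Newton object),
# analytic volumetric tangent (rank-one nodal term plus the
# determinant-Hessian geometric term), minus the follower-load stiffness
fe_tangent <- function(setup, u, ff, p, control) {
  h <- control$fd_step
  Ue <- fe_gather(setup, u)
  vals <- matrix(0, nrow(setup$tri), 36L)
  for (k in 1:6) {
    Up <- Ue
    Up[, k] <- Up[, k] + h
    fek <- fe_internal_iso(setup, Up)$fe
    Up[, k] <- Up[, k] - 2 * h
    fem <- fe_internal_iso(setup, Up)$fe
    vals[, (k - 1L) * 6L + (1:6)] <- (fek - fem) / (2 * h)
  }
  # geometric volumetric term: A * pbar * d2J/du2 (xy blocks only)
  B <- setup$B; Cc <- setup$C
  Ap <- setup$A * ff$pbar
  for (i in 1:3) for (k in 1:3) {
    hik <- Ap * (B[, i] * Cc[, k] - Cc[, i] * B[, k])
    vals[, (k + 2L) * 6L + i] <- vals[, (k + 2L) * 6L + i] + hik       # (x_i, y_k)
    vals[, (k - 1L) * 6L + i + 3L] <- vals[, (k - 1L) * 6L + i + 3L] - hik  # (y_i, x_k)
  }
  i <- as.vector(setup$kI); j <- as.vector(setup$kJ); x <- as.vector(vals)
  if (control$follower_load && p != 0) {
    pt <- fe_pressure(setup, u, p, follower = TRUE, tangent = TRUE)$tangent
    if (!is.null(pt)) { i <- c(i, pt$i); j <- c(j, pt$j); x <- c(x, -pt$x) }
  }
  K <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(setup$ndof, setup$ndof))
  # rank-one nodal pressure term: sum_n kappa_n V_n g_n g_n^T with
  # g_n = dJbar_n/du; build G (nodes x ndof) sparse and form G' D G
  m <- nrow(setup$tri)
  gi <- rep(as.vector(setup$tri), 6L)
  gj <- as.vector(setup$edof[, rep(1:6, each = 3L)])
  gx <- rep(setup$A / 3, 3L * 6L) * as.vector(ff$gvec[, rep(1:6, each = 3L)]) /
    setup$Vn[gi]
  G <- Matrix::sparseMatrix(i = gi, j = gj, x = gx,
                            dims = c(length(setup$Vn), setup$ndof))
  K + Matrix::crossprod(G, (setup$kappa_n * setup$Vn) * G)
}

# Newton solve at one pressure level with residual-norm backtracking;
# returns u, lambda, convergence info
newton_level <- function(setup, Cmat, u, lambda, p, control) {
  eval_state <- function(u, lambda) {
    fi <- try(fe_forces(setup, fe_gather(setup, u)), silent = TRUE)
    if (inherits(fi, "try-error")) return(NULL)   # inverted element / overflow
    fint <- fe_scatter(setup, fi$fe)
    fext <- fe_pressure(setup, u, p, follower = control$follower_load)$f
    Rm <- fint - fext
    R <- Rm + as.numeric(Matrix::t(Cmat) %*% lambda)
    g <- as.numeric(Cmat %*% u)
    list(fi = fi, R = R, Rm = Rm, g = g,
         rnorm = sqrt(sum(R^2) + sum(g^2)), fnorm = sqrt(sum(fext^2)))
  }
  st <- eval_state(u, lambda)
  if (is.null(st)) return(list(ok = FALSE, u = u, lambda = lambda))
  for (it in seq_len(control$max_iter)) {
    if (st$rnorm <= max(control$rel_tol * max(st$fnorm, 1e-300),
                        control$abs_tol))
      return(list(ok = TRUE, u = u, lambda = lambda, iterations = it,
                  residual = st$rnorm, load_norm = st$fnorm))
    K <- fe_tangent(setup, u, st$fi, p, control)
    sys <- apply_rigid_body_constraints(K, st$Rm, Cmat, u, lambda)
    dz <- try(as.numeric(Matrix::solve(sys$A, sys$b)), silent = TRUE)
    if (inherits(dz, "try-error") || any(!is.finite(dz)))
      return(list(ok = FALSE, u = u, lambda = lambda))
    du <- dz[seq_len(setup$ndof)]
    dl <- dz[setup$ndof + seq_len(nrow(Cmat))]
    # backtracking line search: the residual norm must not grow (also guards
    # against inverted elements and material-exponential overflow)
    step <- 1
    accepted <- FALSE
    for (ls in 1:10) {
      stn <- eval_state(u + step * du, lambda + step * dl)
      if (!is.null(stn) && stn$rnorm <= st$rnorm * (1 + 1e-8)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) return(list(ok = FALSE, u = u, lambda = lambda))
    u <- u + step * du
    lambda <- lambda + step * dl
    st <- stn
  }
  list(ok = FALSE, u = u, lambda = lambda)
}

#' Solve the quasi-static pressure cycle for one cross-section
#'
#' Incremental Newton solution of the plane-strain, large-deformation
#' equilibrium of the meshed wall under follower pressure on the lumen
#' boundary, at `n_steps` monotone load levels from zero to the peak of the
#' relative-pressure load. The imaged (diastolic) geometry is the stress-free
#' reference configuration, so the load is the pressure change only. Failed
#' Newton levels are retried with automatic step bisection.
#'
#' @param mesh an [generate_mesh()] result.
#' @param materials material table (default [default_materials()]).
#' @param load a [relative_pressure()] load, or a single peak pressure in kPa.
#' @param n_steps number of monotone load levels up to the peak (default 10).
#' @param control a [solver_control()].
#' @return object of class `"pss_solution"`: list of solution steps (each with
#'   `load`, `load_fraction`, `u` (N x 2 displacements, mm), per-element
#'   Cauchy components `s11, s22, s33, s12`, `von_mises` (kPa) and the
#'   `deformed_lumen` contour), plus the mesh and convergence diagnostics.
#' @export
solve_cycle <- function(mesh, materials = default_materials(), load,
                        n_steps = 10L, control = solver_control()) {
  peak <- if (inherits(load, "pressure_load")) max(load$delta_p) else as.numeric(load)
  if (!is.finite(peak) || peak < 0) stop("invalid peak load")
  setup <- fe_setup(mesh, materials, control)
  Cmat <- rigid_body_constraints(mesh$nodes)
  u <- numeric(setup$ndof)
  lambda <- numeric(3L)

  make_step <- function(u, p) {
    fi <- fe_forces(setup, fe_gather(setup, u), want_cauchy = TRUE)
    vm <- von_mises_components(fi$s11, fi$s22, fi$s33, fi$s12)
    un <- cbind(u[seq(1, setup$ndof, 2)], u[seq(2, setup$ndof, 2)])
    def_lum <- contour(mesh$nodes[mesh$lumen_loop, , drop = FALSE] +
                         un[mesh$lumen_loop, , drop = FALSE], check = FALSE)
    list(load = p, load_fraction = if (peak > 0) p / peak else 0,
         u = un, s11 = fi$s11, s22 = fi$s22, s33 = fi$s33, s12 = fi$s12,
         von_mises = vm, J = fi$J, deformed_lumen = def_lum)
  }

  steps <- list(make_step(u, 0))
  iters <- integer(0)
  residuals <- numeric(0)
  load_norms <- numeric(0)
  if (peak > 0) {
    targets <- peak * seq_len(n_steps) / n_steps
    p_done <- 0
    for (p_target in targets) {
      stack <- p_target
      depth_used <- 0L
      while (length(stack)) {
        pq <- stack[1]
        res <- newton_level(setup, Cmat, u, lambda, pq, control)
        if (res$ok) {
          u <- res$u; lambda <- res$lambda; p_done <- pq
          stack <- stack[-1]
          iters <- c(iters, res$iterations)
          residuals <- c(residuals, res$residual)
          load_norms <- c(load_norms, res$load_norm)
        } else {
          depth_used <- depth_used + 1L
          if (depth_used > control$max_bisect)
            stop(sprintf(paste0("Newton diverged; last converged load ",
                                "%.4f of %.4f kPa after %d bisection levels"),
                         p_done, peak, control$max_bisect))
          stack <- c((p_done + pq) / 2, stack)
        }
      }
      steps[[length(steps) + 1L]] <- make_step(u, p_target)
    }
  }
  structure(list(steps = steps, mesh = mesh, peak_load = peak,
                 n_steps = n_steps, iterations = iters,
                 residuals = residuals, load_norms = load_norms,
                 control = control),
            class = "pss_solution")
}

#' @export
print.pss_solution <- function(x, ...) {
  last <- x$steps[[length(x$steps)]]
  cat(sprintf("<pss_solution> %d steps to %.3f kPa; max von Mises %.2f kPa\n",
              length(x$steps) - 1L, x$peak_load, max(last$von_mises)))
  invisible(x)
}

von_mises_components <- function(s11, s22, s33, s12) {
  sqrt(0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) + 3 * s12^2)
}
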