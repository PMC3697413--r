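# Constitutive laws and the quasi-static nonlinear FE equilibrium solver.
# Element kernels (stress, residual, tangent) live in src/fe_kernels.cpp;
# the functions here are the user-facing surface and the Newton driver.

.hexNodeXi <- matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                       -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1),
                     ncol = 3, byrow = TRUE)

.hexShape <- function(xi) {
  s <- .hexNodeXi
  f1 <- 1 + s[, 1] * xi[1]; f2 <- 1 + s[, 2] * xi[2]; f3 <- 1 + s[, 3] * xi[3]
  list(N = 0.125 * f1 * f2 * f3,
       dN = 0.125 * cbind(s[, 1] * f2 * f3, f1 * s[, 2] * f3,
                          f1 * f2 * s[, 3]))
}

.pp <- function(p) c(p@mu, p@c1, p@c2, p@kappa)
.ap <- function(p) c(p@Tmax, p@Ca0, p@Ca0max, p@B, p@l0, p@lr)

#' Kinematics at a point of a hexahedral element
#'
#' Computes the deformation gradient F = I + du/dX from trilinear shape
#' functions, together with J = det(F), the right Cauchy-Green tensor
#' C = F'F, the fiber stretch lambda = sqrt(a . C a) and the sarcomere
#' length l = lambda * lr.
#'
#' @param X 8 x 3 element nodal reference coordinates, mm.
#' @param u 8 x 3 nodal displacements, mm.
#' @param xi local coordinate in [-1, 1]^3.
#' @param fiber reference unit fiber vector (default x-axis).
#' @param lr unloaded sarcomere length, um.
#' @return list with F, J, C, fiber_stretch, sarcomere_length.
#' @export
kinematics <- function(X, u, xi = c(0, 0, 0), fiber = c(1, 0, 0), lr = 2.04) {
  sh <- .hexShape(xi)
  Jref <- t(X) %*% sh$dN
  if (abs(det(Jref)) < 1e-12) stop("element Jacobian not invertible")
  dNdX <- sh$dN %*% solve(Jref)
  F <- diag(3) + t(u) %*% dNdX
  J <- det(F)
  if (J <= 0) stop("inverted element: det F <= 0")
  C <- t(F) %*% F
  lam <- sqrt(as.numeric(t(fiber) %*% C %*% fiber))
  list(F = F, J = J, C = C, fiber_stretch = lam, sarcomere_length = lam * lr)
}

#' Passive Cauchy stress
#'
#' Nearly incompressible neo-Hookean matrix plus tension-only exponential
#' fiber reinforcement (see [PassiveParams-class] for the energy).
#'
#' @param F 3 x 3 deformation gradient (or a kinematics() list).
#' @param fiber reference unit fiber vector.
#' @param params a [PassiveParams-class].
#' @return symmetric 3 x 3 Cauchy stress, kPa.
#' @export
passiveStress <- function(F, fiber, params = PassiveParams()) {
  if (is.list(F)) F <- F$F
  .cppCauchy(F, fiber, .pp(params), .ap(ActiveParams()), 0)
}

#' Passive strain energy density
#'
#' @inheritParams passiveStress
#' @return energy density, kPa.
#' @export
strainEnergy <- function(F, fiber, params = PassiveParams()) {
  if (is.list(F)) F <- F$F
  .cppPassiveEnergy(F, fiber, .pp(params))
}

#' Length-dependent calcium sensitivity ECa50
#'
#' ECa50(l) = Ca0max / sqrt(exp(B (l - l0)) - 1) for l > l0; +Inf at or
#' below l0 (no tension develops there).
#'
#' @param l sarcomere length, um (vectorized).
#' @param params an [ActiveParams-class].
#' @return ECa50 in uM.
#' @export
calciumSensitivity <- function(l, params = ActiveParams()) {
  out <- rep(Inf, length(l))
  ok <- l > params@l0
  out[ok] <- params@Ca0max / sqrt(exp(params@B * (l[ok] - params@l0)) - 1)
  out
}

#' Active fiber tension
#'
#' T_a = Tmax Ca0^2 / (Ca0^2 + ECa50(l)^2) x activation; zero at or below
#' l0, bounded by Tmax x activation.
#'
#' @param l sarcomere length, um (vectorized).
#' @param activation non-negative activation scalar (psi_a * Ct).
#' @param params an [ActiveParams-class].
#' @return tension in kPa.
#' @export
activeTension <- function(l, activation, params = ActiveParams()) {
  if (activation < 0) stop("activation must be non-negative")
  eca <- calciumSensitivity(l, params)
  frac <- params@Ca0^2 / (params@Ca0^2 + eca^2)
  frac[!is.finite(eca)] <- 0
  params@Tmax * frac * activation
}

#' Total Cauchy stress
#'
#' T = T_passive + T_a (a x a), with a the (renormalized) push-forward of
#' the reference fiber direction.
#'
#' @param F 3 x 3 deformation gradient (or a kinematics() list).
#' @param fiber reference unit fiber vector.
#' @param passive a [PassiveParams-class].
#' @param tension active fiber tension T_a, kPa.
#' @return symmetric 3 x 3 Cauchy stress, kPa.
#' @export
totalStress <- function(F, fiber, passive = PassiveParams(), tension = 0) {
  if (is.list(F)) F <- F$F
  sig <- passiveStress(F, fiber, passive)
  if (tension != 0) {
    a <- as.numeric(F %*% fiber)
    a <- a / sqrt(sum(a^2))
    sig <- sig + tension * tcrossprod(a)
  }
  sig
}

.dofIndex <- function(node, dof) 3L * (node - 1L) + dof

#' Solve quasi-static FE equilibrium
#'
#' Newton iteration on the residual (internal stress divergence minus
#' applied nodal forces) with a consistent sparse tangent and backtracking
#' line search. External forces may be a fixed N x 3 matrix or a function of
#' the current displacement (re-evaluated every Newton iteration), which is
#' how configuration-dependent image forces enter.
#'
#' @param mesh a [HexMesh-class].
#' @param fibers a [FiberField-class].
#' @param passive a [PassiveParams-class].
#' @param active an [ActiveParams-class].
#' @param external_forces N x 3 matrix, or function(u) returning one.
#' @param activation non-negative activation scalar applied uniformly.
#' @param external_stiffness optional function(u) returning a sparse
#'   3N x 3N matrix added to the tangent: the negative Jacobian of the
#'   external forces (e.g. the Gauss-Newton stiffness of the image energy).
#' @param constraints data.frame(node, dof) of fixed (zero) displacement
#'   components; must remove all rigid-body modes.
#' @param u0 initial N x 3 displacement guess.
#' @param tol relative residual tolerance.
#' @param max_iter Newton iteration cap.
#' @return list with \code{u} (N x 3), \code{residual} (relative), and
#'   \code{iterations}.
#' @export
solveEquilibrium <- function(mesh, fibers, passive = PassiveParams(),
                             active = ActiveParams(), external_forces = NULL,
                             external_stiffness = NULL,
                             activation = 0, constraints = basalConstraints(mesh),
                             u0 = NULL, tol = 1e-8, max_iter = 50L) {
  nn <- nrow(mesh@nodes)
  if (is.null(u0)) u0 <- matrix(0, nn, 3)
  forces_fun <- if (is.function(external_forces)) external_forces
                else function(u) if (is.null(external_forces))
                  matrix(0, nn, 3) else external_forces
  fixed <- .dofIndex(constraints$node, constraints$dof)
  free <- setdiff(seq_len(3L * nn), fixed)
  pp <- .pp(passive); ap <- .ap(active)
  u <- u0

  resid_vec <- function(u, fext) {
    asm <- .cppAssemble(mesh@nodes, mesh@elements, u, fibers@vectors,
                        activation, pp, ap, FALSE)
    as.numeric(t(asm$fint - fext))
  }

  rel <- Inf
  for (it in seq_len(max_iter)) {
    fext <- forces_fun(u)
    asm <- .cppAssemble(mesh@nodes, mesh@elements, u, fibers@vectors,
                        activation, pp, ap, TRUE)
    r <- as.numeric(t(asm$fint - fext))[free]
    scale <- max(sqrt(sum(as.numeric(asm$fint)^2)),
                 sqrt(sum(as.numeric(fext)^2)), 1e-10)
    rel <- sqrt(sum(r^2)) / scale
    # absolute floor: an unloaded state with machine-zero forces is in
    # equilibrium regardless of the force scale
    if (rel <= tol || sqrt(sum(r^2)) < 1e-9)
      return(list(u = u, residual = rel, iterations = it - 1L))
    K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                              dims = c(3L * nn, 3L * nn))
    if (!is.null(external_stiffness)) K <- K + external_stiffness(u)
    du_free <- as.numeric(Matrix::solve(K[free, free, drop = FALSE], -r))
    du <- numeric(3L * nn)
    du[free] <- du_free
    du_mat <- matrix(du, nn, 3, byrow = TRUE)
    # backtracking on the true residual norm (forces re-evaluated)
    rn0 <- sqrt(sum(r^2))
    alpha <- 1
    repeat {
      u_try <- u + alpha * du_mat
      rn <- tryCatch(
        sqrt(sum(resid_vec(u_try, forces_fun(u_try))[free]^2)),
        error = function(e) Inf)
      if (rn < rn0 || alpha <= 1 / 64) break
      alpha <- alpha / 2
    }
    if (!is.finite(rn)) stop("solver error: line search failed (inverted element)")
    u <- u_try
  }
  # final check after the last update
  fext <- forces_fun(u)
  r <- resid_vec(u, fext)[free]
  scale <- max(sqrt(sum(as.numeric(fext)^2)), 1e-10)
  rel <- sqrt(sum(r^2)) / scale
  if (rel > tol)
    stop(sprintf("solver error: no convergence after %d iterations (relative residual %.3g)",
                 max_iter, rel))
  list(u = u, residual = rel, iterations = max_iter)
}
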