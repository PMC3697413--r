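# Registration engine: image energy and nodal forces on the mesh quadrature,
# the subject-specific activation scalar from mean intensity mismatch, the
# penalty schedules, and the pseudo-time driver.

# Sparse operator A (nodes x quadrature points) with A[n, q] = N_a(q) for
# n = element node a; interpolation to qp is t(A) %*% u, nodal assembly of
# per-qp vector data is A %*% c.
.assemblyOperator <- function(mesh, N) {
  ne <- nrow(mesh@elements)
  qp <- rep(seq_len(ne * 8L), times = 8L) # for a-major below
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (a in 1:8) {
    i <- c(i, rep(mesh@elements[, a], each = 8L))
    j <- c(j, seq_len(ne * 8L))
    x <- c(x, rep(N[, a], times = ne))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(nrow(mesh@nodes), ne * 8L))
}

# Cached per-mesh quadrature context for image terms.
.imageContext <- function(mesh, template, target,
                          interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  quad <- .cppQuadrature(mesh@nodes, mesh@elements)
  ctx <- list(points = quad$points, weights = as.numeric(quad$weights),
              N = quad$N, elements = mesh@elements,
              A = .assemblyOperator(mesh, quad$N))
  if (interp == "cubic") {
    ssp <- .splineCoeffs(target)
    ctx$Tq <- .splineSample(.splineCoeffs(template), ctx$points)
    ctx$sampleS <- function(p) .splineSample(ssp, p)
    ctx$gradS <- function(p) .splineSample(ssp, p, gradient = TRUE)
    ctx$hessS <- function(p) .splineSample(ssp, p, what = "hessian")
  } else {
    ctx$Tq <- sampleIntensity(template, ctx$points)
    ctx$sampleS <- function(p) sampleIntensity(target, p)
    ctx$gradS <- function(p) sampleGradient(target, p)
    ctx$hessS <- function(p) matrix(0, nrow(p), 6) # piecewise-linear cells
  }
  ctx
}

.qpDeformed <- function(ctx, u) {
  ctx$points + as.matrix(Matrix::t(ctx$A) %*% u)
}

#' Image-based registration energy
#'
#' Gauss-quadrature integral over the mesh of psi/2 (T(X) - S(phi(X)))^2,
#' with the template sampled at reference quadrature positions and the
#' target at the deformed positions.
#'
#' @param template,target [Image3D-class] volumes.
#' @param mesh a [HexMesh-class].
#' @param u N x 3 nodal displacements, mm.
#' @param psi non-negative image penalty.
#' @param interp interpolant of the image functional ("cubic" default).
#' @param ctx optional precomputed sampling context (internal reuse).
#' @return scalar energy.
#' @export
imageEnergy <- function(template, target, mesh, u = NULL, psi = 1,
                        interp = "cubic", ctx = NULL) {
  if (psi < 0) stop("psi must be non-negative")
  if (is.null(ctx)) ctx <- .imageContext(mesh, template, target, interp)
  if (is.null(u)) u <- matrix(0, nrow(mesh@nodes), 3)
  Sq <- ctx$sampleS(.qpDeformed(ctx, u))
  sum(0.5 * psi * (ctx$Tq - Sq)^2 * ctx$weights)
}

#' Image-based nodal forces
#'
#' Nodal assembly of psi (T(X) - S(phi)) dS/dphi over the quadrature rule;
#' equals minus the gradient of [imageEnergy()] with respect to the nodal
#' displacements.
#'
#' @inheritParams imageEnergy
#' @return N x 3 matrix of nodal forces.
#' @export
imageForces <- function(template, target, mesh, u = NULL, psi = 1,
                        interp = "cubic", ctx = NULL) {
  if (psi < 0) stop("psi must be non-negative")
  if (is.null(ctx)) ctx <- .imageContext(mesh, template, target, interp)
  if (is.null(u)) u <- matrix(0, nrow(mesh@nodes), 3)
  xq <- .qpDeformed(ctx, u)
  Sq <- ctx$sampleS(xq)
  Gq <- ctx$gradS(xq)
  C <- Gq * (psi * (ctx$Tq - Sq) * ctx$weights)
  as.matrix(ctx$A %*% C)
}

# Stiffness of the image energy: per quadrature point the 3 x 3 block
# M = psi w [gradS gradS' - (T - S) hessS], assembled into element blocks
# N_a N_b M. With the C2 spline interpolant this is the exact second
# variation, giving quadratic Newton convergence of the registration steps.
.imageStiffness <- function(mesh, u, psi, ctx) {
  nn <- nrow(mesh@nodes)
  if (psi <= 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(3L * nn, 3L * nn)))
  xq <- .qpDeformed(ctx, u)
  Gq <- ctx$gradS(xq)
  Hq <- ctx$hessS(xq)
  Dq <- ctx$Tq - ctx$sampleS(xq)
  ne <- nrow(ctx$elements)
  Nq <- ctx$N # 8 (gp) x 8 (node)
  w <- ctx$weights
  # element dof ids (24 per element)
  dofs <- t(apply(ctx$elements, 1, function(nd) as.vector(rbind(
    3L * (nd - 1L) + 1L, 3L * (nd - 1L) + 2L, 3L * (nd - 1L) + 3L))))
  ii <- jj <- integer(ne * 576L); xx <- numeric(ne * 576L)
  pos <- 0L
  NN <- lapply(1:8, function(q) tcrossprod(Nq[q, ]))
  for (e in seq_len(ne)) {
    Ke <- matrix(0, 24, 24)
    for (q in 1:8) {
      k <- (e - 1L) * 8L + q
      g <- Gq[k, ]
      H <- matrix(c(Hq[k, 1], Hq[k, 4], Hq[k, 5],
                    Hq[k, 4], Hq[k, 2], Hq[k, 6],
                    Hq[k, 5], Hq[k, 6], Hq[k, 3]), 3, 3)
      M <- (psi * w[k]) * (tcrossprod(g) - Dq[k] * H)
      Ke <- Ke + kronecker(NN[[q]], M)
    }
    ii[pos + 1:576] <- rep(dofs[e, ], times = 24L)
    jj[pos + 1:576] <- rep(dofs[e, ], each = 24L)
    xx[pos + 1:576] <- as.numeric(Ke)
    pos <- pos + 576L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3L * nn, 3L * nn))
}

#' Mean template-target intensity mismatch (Ct)
#'
#' Per-element mean of (T - S(phi)) at the quadrature points, then the
#' arithmetic mean over all elements. Signed by default; the absolute-value
#' reading is available via \code{absolute = TRUE}.
#'
#' @inheritParams imageEnergy
#' @param absolute take |T - S| per quadrature point before averaging.
#' @param interp interpolant ("cubic" default).
#' @param ctx optional precomputed sampling context (internal reuse).
#' @return scalar Ct in intensity units.
#' @export
averageIntensityMismatch <- function(template, target, mesh, u = NULL,
                                     absolute = FALSE, interp = "cubic",
                                     ctx = NULL) {
  if (nrow(mesh@elements) == 0L) stop("mesh is empty")
  if (is.null(ctx)) ctx <- .imageContext(mesh, template, target, interp)
  if (is.null(u)) u <- matrix(0, nrow(mesh@nodes), 3)
  Sq <- ctx$sampleS(.qpDeformed(ctx, u))
  diff <- ctx$Tq - Sq
  if (absolute) diff <- abs(diff)
  elem_mean <- rowMeans(matrix(diff, ncol = 8, byrow = TRUE))
  mean(elem_mean)
}

#' Penalty schedules at a pseudo-time
#'
#' psi ramps linearly over the whole analysis; psi_a ramps linearly until
#' the knot (default 2/3 of the analysis) and is then held constant.
#'
#' @param t pseudo-time in [0, 1].
#' @param schedule a [PenaltySchedule-class].
#' @return list with \code{psi} and \code{psi_a}.
#' @export
penaltySchedule <- function(t, schedule = PenaltySchedule()) {
  if (any(t < 0 | t > 1)) stop("pseudo-time must lie in [0, 1]")
  list(psi = t * schedule@psi_max,
       psi_a = pmin(t / schedule@knot, 1) * schedule@psi_a_max)
}

#' Register a template volume to a target volume
#'
#' Pseudo-time driver of hyperelastic warping: at each step the penalties
#' are updated, the activation scalar is set to psi_a * Ct (clamped at
#' zero), and the FE model is equilibrated under the image forces with the
#' active fiber stress in the constitutive update. The final displacement
#' field defines the recovered deformation map.
#'
#' @param template,target [Image3D-class] volumes (end-diastole,
#'   end-systole).
#' @param mesh a [HexMesh-class] built on the template.
#' @param fibers a [FiberField-class].
#' @param passive a [PassiveParams-class].
#' @param active an [ActiveParams-class].
#' @param schedule a [PenaltySchedule-class].
#' @param n_steps number of equal pseudo-time increments (>= 2).
#' @param interp interpolant of the image functional ("cubic" default; the
#'   C2 spline keeps the image forces continuously differentiable so the
#'   Newton iterations can converge tightly).
#' @param active_on logical; FALSE ablates the active contraction.
#' @param ct_absolute drive the activation with the absolute per-point
#'   mismatch |T - S| (default) rather than the signed mean. The signed
#'   reading switches contraction off permanently once systolic
#'   partial-volume brightening makes the registered target locally
#'   brighter than the template; the magnitude reading keeps the active
#'   drive tied to the amount of misregistration, which is the behavior
#'   the method's sensitivity studies document. Both are exposed.
#' @param constraints data.frame(node, dof); defaults to
#'   [basalConstraints()].
#' @param newton_tol,max_iter passed to [solveEquilibrium()].
#' @param verbose print per-step progress.
#' @return A [RegistrationResult-class]; the stored step at t = 0 is the
#'   undeformed state.
#' @export
register <- function(template, target, mesh, fibers,
                     passive = PassiveParams(), active = ActiveParams(),
                     schedule = PenaltySchedule(), n_steps = 30L,
                     interp = "cubic", ct_absolute = TRUE,
                     active_on = TRUE, constraints = basalConstraints(mesh),
                     newton_tol = 1e-8, max_iter = 40L, verbose = FALSE) {
  if (n_steps < 2L) stop("n_steps must be >= 2")
  ctx <- .imageContext(mesh, template, target, interp)
  nn <- nrow(mesh@nodes)
  u <- matrix(0, nn, 3)
  times <- seq(0, 1, length.out = n_steps + 1L)
  disps <- vector("list", n_steps + 1L)
  ct_tr <- en_tr <- mis_tr <- numeric(n_steps + 1L)
  conv <- logical(n_steps + 1L)
  disps[[1]] <- u
  ct_tr[1] <- averageIntensityMismatch(template, target, mesh, u,
                                       absolute = ct_absolute, ctx = ctx)
  mis_tr[1] <- imageEnergy(template, target, mesh, u, psi = 1, ctx = ctx)
  en_tr[1] <- 0
  conv[1] <- TRUE

  for (k in seq_len(n_steps)) {
    t_k <- times[k + 1L]
    pen <- penaltySchedule(t_k, schedule)
    ct <- averageIntensityMismatch(template, target, mesh, u,
                                   absolute = ct_absolute, ctx = ctx)
    activation <- if (active_on) max(0, pen$psi_a * ct) else 0
    force_fun <- function(uu)
      imageForces(template, target, mesh, uu, psi = pen$psi, ctx = ctx)
    stiff_fun <- function(uu)
      .imageStiffness(mesh, uu, pen$psi, ctx)
    sol <- tryCatch(
      solveEquilibrium(mesh, fibers, passive, active,
                       external_forces = force_fun,
                       external_stiffness = stiff_fun, activation = activation,
                       constraints = constraints, u0 = u, tol = newton_tol,
                       max_iter = max_iter),
      error = function(e)
        stop(sprintf("registration error at step %d (t = %.3f): %s",
                     k, t_k, conditionMessage(e)), call. = FALSE))
    u <- sol$u
    disps[[k + 1L]] <- u
    ct_tr[k + 1L] <- ct
    en_tr[k + 1L] <- imageEnergy(template, target, mesh, u, psi = pen$psi,
                                 ctx = ctx)
    mis_tr[k + 1L] <- imageEnergy(template, target, mesh, u, psi = 1,
                                  ctx = ctx)
    conv[k + 1L] <- TRUE
    if (verbose)
      message(sprintf(
        "step %2d/%d t=%.3f Ct=%8.3f act=%8.4f mismatch=%10.1f iters=%d",
        k, n_steps, t_k, ct, activation, mis_tr[k + 1L], sol$iterations))
  }
  new("RegistrationResult", times = times, displacements = disps,
      ct_trace = ct_tr, energy_trace = en_tr, mismatch_trace = mis_tr,
      converged = conv)
}

#' Final displacement field of a registration
#'
#' @param result a [RegistrationResult-class].
#' @return N x 3 matrix.
#' @export
finalDisplacement <- function(result) {
  result@displacements[[length(result@displacements)]]
}

#' Fractional image-energy reduction achieved by a registration
#'
#' @param result a [RegistrationResult-class].
#' @return 1 - (final mismatch) / (initial mismatch).
#' @export
energyReduction <- function(result) {
  n <- length(result@mismatch_trace)
  1 - result@mismatch_trace[n] / result@mismatch_trace[1]
}
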