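test_that("kinematics recovers identity and affine deformation gradients", {
  mesh <- unitCubeMesh()
  X <- mesh@nodes
  k0 <- kinematics(X, matrix(0, 8, 3))
  expect_equal(k0$F, diag(3))
  expect_equal(k0$J, 1)
  expect_equal(k0$fiber_stretch, 1)
  expect_equal(k0$sarcomere_length, 2.04)

  u <- cbind(0.1 * X[, 1], 0, 0)
  k1 <- kinematics(X, u, xi = c(0.3, -0.2, 0.5))
  expect_equal(k1$F, diag(c(1.1, 1, 1)), tolerance = 1e-12)

  set.seed(3)
  A <- matrix(rnorm(9, 0, 0.1), 3, 3)
  u2 <- X %*% t(A)
  a <- c(1, 0, 0)
  k2 <- kinematics(X, u2, fiber = a)
  lam_direct <- sqrt(as.numeric(t(a) %*% (t(diag(3) + A) %*% (diag(3) + A)) %*% a))
  expect_equal(k2$fiber_stretch, lam_direct, tolerance = 1e-12)
})

test_that("inverted elements are reported", {
  mesh <- unitCubeMesh()
  u <- cbind(-1.5 * mesh@nodes[, 1], 0, 0)
  expect_error(kinematics(mesh@nodes, u), "inverted")
})

test_that("reference state is stress-free and fiber direction is stiffer", {
  a <- c(1, 0, 0)
  expect_equal(passiveStress(diag(3), a), matrix(0, 3, 3), tolerance = 1e-14)
  along <- passiveStress(diag(c(1.1, 1, 1)), a)
  across <- passiveStress(diag(c(1, 1.1, 1)), a)
  expect_gt(along[1, 1], across[2, 2])
})

test_that("passive stress is the derivative of the stored energy", {
  set.seed(10)
  pp <- PassiveParams()
  for (rep in 1:50) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.06), 3, 3)
    if (det(F) <= 0.2) next
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    P <- warpstrain:::.cppPK1(F, a, warpstrain:::.pp(pp),
                              warpstrain:::.ap(ActiveParams()), 0)
    Pfd <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Pfd[i, j] <- (strainEnergy(Fp, a, pp) - strainEnergy(Fm, a, pp)) / (2 * h)
    }
    expect_lt(max(abs(P - Pfd)) / max(max(abs(P)), 1e-8), 1e-5)
  }
})

test_that("stresses are objective under superposed rigid rotation", {
  set.seed(4)
  pp <- warpstrain:::.pp(PassiveParams())
  ap <- warpstrain:::.ap(ActiveParams())
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.08), 3, 3)
    if (det(F) <= 0.2) next
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    Q <- randomRotation(rep)
    s1 <- warpstrain:::.cppCauchy(Q %*% F, a, pp, ap, 0.4)
    s2 <- Q %*% warpstrain:::.cppCauchy(F, a, pp, ap, 0.4) %*% t(Q)
    expect_lt(max(abs(s1 - s2)), 1e-10)
  }
})

test_that("calcium sensitivity follows the square-root elastance form", {
  ap <- ActiveParams()
  # l -> l0+ diverges, so tension vanishes there
  expect_equal(calciumSensitivity(ap@l0, ap), Inf)
  expect_gt(calciumSensitivity(ap@l0 + 1e-6, ap), 1e3)
  # closed form: exp term = 2 at l = l0 + ln(2)/B
  l2 <- ap@l0 + log(2) / ap@B
  expect_equal(calciumSensitivity(l2, ap), 4.35, tolerance = 1e-12)
  # strictly decreasing on (l0, 3]
  l <- seq(ap@l0 + 1e-3, 3, length.out = 100)
  expect_true(all(diff(calciumSensitivity(l, ap)) < 0))
})

test_that("active tension vanishes at l0, is bounded and matches the scalar form", {
  ap <- ActiveParams()
  expect_equal(activeTension(1.58, 1, ap), 0)
  expect_equal(activeTension(1.2, 1, ap), 0)       # below l0: continuous at 0
  expect_equal(activeTension(2.1, 0, ap), 0)       # no activation
  l <- seq(1.2, 3, length.out = 200)
  Ta <- activeTension(l, 0.7, ap)
  expect_true(all(Ta >= 0))
  expect_true(all(Ta <= ap@Tmax * 0.7 + 1e-12))
  # independent scalar evaluation at l = 2.5
  eca <- 4.35 / sqrt(exp(4.75 * (2.5 - 1.58)) - 1)
  expect_equal(activeTension(2.5, 0.7, ap),
               135.7 * 4.35^2 / (4.35^2 + eca^2) * 0.7, tolerance = 1e-12)
  expect_error(activeTension(2.0, -0.1, ap), "activation")
})

test_that("total stress adds a rank-one active term along the pushed fiber", {
  a <- c(1, 0, 0)
  expect_equal(totalStress(diag(3), a, tension = 0.8),
               passiveStress(diag(3), a) + diag(c(0.8, 0, 0)),
               tolerance = 1e-12)
  # trace identity: tr(T - Tp) = Ta for any unit direction
  set.seed(5)
  F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3, 3)
  for (rep in 1:5) {
    a <- rnorm(3); a <- a / sqrt(sum(a^2))
    d <- totalStress(F, a, tension = 1.3) - passiveStress(F, a)
    expect_equal(sum(diag(d)), 1.3, tolerance = 1e-10)
  }
})

test_that("zero load gives zero displacement", {
  mesh <- unitCubeMesh()
  sol <- solveEquilibrium(mesh, xFiber(),
                          constraints = cubeSymmetryConstraints(mesh))
  expect_equal(sol$u, matrix(0, 8, 3))
  expect_equal(sol$iterations, 0)
})

test_that("patch test matches a single-point constitutive inversion", {
  mesh <- unitCubeMesh()
  cons <- cubeSymmetryConstraints(mesh)
  t0 <- 0.5
  fext <- matrix(0, 8, 3)
  fext[mesh@nodes[, 1] == 1, 1] <- t0 / 4
  sol <- solveEquilibrium(mesh, xFiber(), external_forces = fext,
                          constraints = cons)
  F11 <- 1 + max(sol$u[mesh@nodes[, 1] == 1, 1])
  F22 <- 1 + min(sol$u[mesh@nodes[, 2] == 1, 2])
  # homogeneous state
  expect_lt(diff(range(sol$u[mesh@nodes[, 1] == 1, 1])), 1e-10)
  # independent 2-variable Newton on P11 = t0, P22 = P33 = 0
  pp <- warpstrain:::.pp(PassiveParams())
  ap <- warpstrain:::.ap(ActiveParams())
  obj <- function(v) {
    P <- warpstrain:::.cppPK1(diag(c(v[1], v[2], v[2])), c(1, 0, 0), pp, ap, 0)
    c(P[1, 1] - t0, P[2, 2])
  }
  v <- c(1.05, 0.99)
  for (i in 1:60) {
    r <- obj(v)
    if (max(abs(r)) < 1e-13) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      vp <- v; vp[j] <- vp[j] + 1e-7
      J[, j] <- (obj(vp) - r) / 1e-7
    }
    v <- v - solve(J, r)
  }
  expect_lt(abs(F11 - v[1]), 1e-6)
  expect_lt(abs(F22 - v[2]), 1e-6)
})

test_that("Newton convergence is superlinear on the patch test", {
  mesh <- unitCubeMesh()
  cons <- cubeSymmetryConstraints(mesh)
  fext <- matrix(0, 8, 3)
  fext[mesh@nodes[, 1] == 1, 1] <- 0.2
  # record the residual sequence by running the solver manually
  fib <- xFiber()
  pp <- warpstrain:::.pp(PassiveParams())
  ap <- warpstrain:::.ap(ActiveParams())
  fixed <- 3L * (cons$node - 1L) + cons$dof
  free <- setdiff(1:24, fixed)
  u <- matrix(0, 8, 3)
  rn <- c()
  for (it in 1:8) {
    asm <- warpstrain:::.cppAssemble(mesh@nodes, mesh@elements, u,
                                     fib@vectors, 0, pp, ap, TRUE)
    r <- as.numeric(t(asm$fint - fext))[free]
    rn <- c(rn, sqrt(sum(r^2)))
    if (rn[it] < 1e-12) break
    K <- Matrix::sparseMatrix(i = asm$i, j = asm$j, x = asm$x,
                              dims = c(24, 24))
    du <- numeric(24)
    du[free] <- as.numeric(Matrix::solve(K[free, free], -r))
    u <- u + matrix(du, 8, 3, byrow = TRUE)
  }
  ratios <- rn[-1] / rn[-length(rn)]
  # ratios decrease towards zero: faster than any fixed linear rate
  expect_true(all(diff(ratios[ratios > 0]) < 0))
  expect_lt(tail(rn, 1), 1e-10)
})

test_that("uniform activation thickens the wall and shrinks the cavity", {
  mesh <- buildLVMesh(divisions = c(12, 4, 2))
  fr <- localFrames(mesh)
  fib <- assignFibers(mesh, c(-82, 0, 80), fr)
  sol <- solveEquilibrium(mesh, fib, activation = 0.05)
  st <- recoveredStrains(mesh, sol$u, fr)
  expect_gt(mean(st[, "radial"]), 0)          # thickening
  expect_lt(mean(st[, "circumferential"]), 0) # shortening
  # endocardial ring moves toward the axis
  r0 <- sqrt(mesh@nodes[, 1]^2 + mesh@nodes[, 2]^2)
  endo <- which(abs(r0 - min(r0)) < 1e-6)
  r1 <- sqrt((mesh@nodes[endo, 1] + sol$u[endo, 1])^2 +
             (mesh@nodes[endo, 2] + sol$u[endo, 2])^2)
  expect_lt(mean(r1 - r0[endo]), 0)
})
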