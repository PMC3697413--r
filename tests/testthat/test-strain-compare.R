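test_that("Green-Lagrange strain closed forms", {
  expect_equal(greenLagrange(diag(3)), matrix(0, 3, 3))
  lam <- 1.17
  E <- greenLagrange(diag(c(lam, 1, 1)))
  expect_equal(E[1, 1], (lam^2 - 1) / 2)
  expect_equal(E[2, 2], 0)
  Q <- randomRotation(2)
  expect_lt(max(abs(greenLagrange(Q))), 1e-12)
})

test_that("projected strain is a double contraction, sign-invariant in d", {
  E <- diag(c(0.2, -0.1, 0.05))
  expect_equal(projectStrain(E, c(1, 0, 0)), 0.2)
  set.seed(6)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3, 3); E <- (A + t(A)) / 2
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    direct <- sum(outer(d, d) * E)
    expect_equal(projectStrain(E, d), direct, tolerance = 1e-14)
    expect_equal(projectStrain(E, -d), projectStrain(E, d))
  }
  expect_error(projectStrain(E, c(1, 1, 0)), "unit")
})

test_that("sampling layout yields 12 rows per direction per slice", {
  mesh <- buildLVMesh(divisions = c(12, 4, 3))
  strains <- cbind(circumferential = rep(0.1, nrow(mesh@elements) * 8),
                   radial = rep(-0.2, nrow(mesh@elements) * 8))
  tab <- sampleHarpGrid(mesh, strains, slices = 2L)
  expect_equal(sum(tab$direction == "circumferential"), 12L)
  expect_equal(sum(tab$direction == "radial"), 12L)
  expect_equal(nrow(tab), 24L)
  # averaging a constant field returns the constant
  expect_true(all(tab$value[tab$direction == "circumferential"] == 0.1))
  expect_true(all(tab$value[tab$direction == "radial"] == -0.2))
  # all slices: 24 rows per slice, always
  full <- sampleHarpGrid(mesh, strains)
  expect_equal(nrow(full), 24L * 4L)
})

test_that("sampled phantom truth is close to the analytic strain at cell centers", {
  spec <- PhantomSpec()
  mesh <- phantomMesh(spec, c(16L, 6L, 3L))
  frames <- localFrames(mesh)
  tab <- phantomTruth(spec, mesh, frames)
  # dual-route oracle: recompute each cell value from scratch with the
  # scalar-path functions (per-point analytic F -> greenLagrange ->
  # projectStrain -> plain mean), independent of the vectorized
  # projectedStrains/sampleHarpGrid path
  quad <- warpstrain:::.cppQuadrature(mesh@nodes, mesh@elements)
  qp_slice <- rep(mesh@slice_index, each = 8)
  qp_region <- rep(mesh@region, each = 8)
  qp_depth <- as.character(warpstrain:::.depthLabel(mesh@wall_depth))
  set.seed(31)
  for (i in sample(nrow(tab), 12)) {
    sel <- which(qp_slice == tab$slice[i] & qp_region == tab$region[i] &
                 qp_depth == tab$depth[i])
    vals <- vapply(sel, function(k) {
      def <- analyticDeformation(quad$points[k, , drop = FALSE], spec)
      E <- greenLagrange(matrix(def$F[1, ], 3, 3))
      d <- if (tab$direction[i] == "circumferential")
        frames@circumferential[k, ] else frames@radial[k, ]
      projectStrain(E, d)
    }, numeric(1))
    expect_lt(abs(tab$value[i] - mean(vals)), 1e-10)
    # and the cell mean is representative of its midpoint to phantom scale
    expect_lt(abs(tab$value[i] - vals[which.min(abs(vals - mean(vals)))]),
              0.03)
  }
})

test_that("percent RMSE arithmetic, exclusions and scale invariance", {
  expect_equal(as.numeric(percentRMSE(c(0.2, 0.3), c(0.2, 0.3))), 0)
  expect_equal(as.numeric(percentRMSE(0.2, 0.1)), 0.5)
  expect_equal(as.numeric(percentRMSE(c(0.2, 0.2), c(0.1, 0.3))), 0.5)
  # both grouping variants coincide for equal references
  expect_equal(as.numeric(percentRMSE(c(0.2, 0.2), c(0.1, 0.3),
                                      variant = "ratio_of_sums")), 0.5)
  # scale invariance
  r <- c(0.1, -0.25, 0.3); p <- c(0.12, -0.2, 0.36)
  expect_equal(as.numeric(percentRMSE(3 * r, 3 * p)),
               as.numeric(percentRMSE(r, p)))
  # exclusion of near-zero references is counted
  out <- percentRMSE(c(0.005, 0.2), c(0.1, 0.1))
  expect_equal(attr(out, "n_excluded"), 1L)
  expect_error(percentRMSE(c(0.001, 0.002), c(1, 2)), "metric error")
})

test_that("R^2 is 1 for affine relations, near 0 under independence", {
  x <- seq(-1, 1, length.out = 20)
  expect_equal(rSquared(x, 2 * x + 1), 1)
  expect_equal(rSquared(5 * x - 2, -0.3 * x), 1)
  set.seed(8)
  xr <- rnorm(1e4); yr <- rnorm(1e4)
  expect_lt(rSquared(xr, yr), 0.01)
  expect_equal(rSquared(xr, 3 * yr + 2), rSquared(xr, yr))
  expect_error(rSquared(rep(1, 5), 1:5), "metric error")
})

test_that("Bland-Altman statistics detect bias and proportional trends", {
  x <- seq(0.05, 0.4, length.out = 25)
  b0 <- blandAltman(x, x)
  expect_equal(b0$mean_diff, 0)
  expect_equal(b0$loa_lower, 0)
  expect_equal(b0$slope, 0)
  b1 <- blandAltman(x, x + 0.1)
  expect_equal(b1$mean_diff, 0.1)
  expect_equal(b1$sd_diff, 0)
  # proportional underestimation: d = -0.2 x, m = 0.9 x -> slope -2/9
  b2 <- blandAltman(x, 0.8 * x)
  expect_lt(b2$slope, 0)
  expect_equal(b2$slope, -0.2 / 0.9, tolerance = 1e-10)
})

test_that("paired t-test matches the textbook formula and the power check", {
  x <- c(0.10, 0.22, 0.31, 0.18, 0.25)
  y <- c(0.12, 0.20, 0.35, 0.21, 0.24)
  d <- y - x
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_formula <- 2 * pt(-abs(tstat), df = length(d) - 1)
  expect_equal(pairedTTest(x, y), p_formula, tolerance = 1e-10)
  expect_equal(pairedTTest(x, x), 1)
  set.seed(9)
  x2 <- rnorm(50, 0.2, 0.01)
  expect_lt(pairedTTest(x2, x2 + 0.05 + rnorm(50, 0, 0.005)), 0.01)
})

test_that("comparison report is exact on identical tables and degenerate-safe", {
  mesh <- buildLVMesh(divisions = c(12, 4, 3))
  strains <- cbind(circumferential = rnorm(nrow(mesh@elements) * 8, -0.1, 0.04),
                   radial = rnorm(nrow(mesh@elements) * 8, 0.15, 0.05))
  tab <- sampleHarpGrid(mesh, strains)
  cmp <- compareStrains(tab, tab)
  expect_equal(cmp$circumferential$r_squared, 1)
  expect_equal(cmp$pooled$percent_rmse, 0)
  expect_equal(cmp$pooled$bland_altman$mean_diff, 0)
  expect_equal(cmp$pooled$t_test_p, 1)
  # all-zero tables: R^2 and %RMSE undefined -> NA, no error
  z <- tab; z$value <- 0
  cmpz <- compareStrains(z, z)
  expect_true(is.na(cmpz$pooled$r_squared))
  expect_true(is.na(cmpz$pooled$percent_rmse))
})

test_that("strain tables round-trip through CSV", {
  mesh <- buildLVMesh(divisions = c(12, 4, 3))
  strains <- cbind(circumferential = rnorm(nrow(mesh@elements) * 8),
                   radial = rnorm(nrow(mesh@elements) * 8))
  tab <- sampleHarpGrid(mesh, strains)
  path <- tempfile(fileext = ".csv")
  writeStrainTable(tab, path)
  back <- readStrainTable(path)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_identical(back$region, tab$region)
  unlink(path)
})
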