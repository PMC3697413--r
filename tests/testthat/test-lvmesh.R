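test_that("mesh counts follow the open-tube topology formula", {
  mesh <- buildLVMesh(divisions = c(16, 8, 3))
  expect_equal(nrow(mesh@elements), 16 * 8 * 3)
  expect_equal(nrow(mesh@nodes), 16 * 9 * 4)
  quad <- warpstrain:::.cppQuadrature(mesh@nodes, mesh@elements)
  expect_gt(min(quad$weights), 0) # positive reference Jacobians
})

test_that("default mesh wall volume is within 2% of the analytic shell", {
  mesh <- buildLVMesh()
  expect_lt(abs(meshVolume(mesh) / analyticWallVolume(mesh@geometry) - 1),
            0.02)
})

test_that("wall volume error decreases monotonically under refinement", {
  err <- sapply(list(c(8, 3, 1), c(16, 6, 2), c(32, 12, 4)), function(dv) {
    m <- buildLVMesh(divisions = dv)
    abs(meshVolume(m) / analyticWallVolume(m@geometry) - 1)
  })
  expect_true(all(diff(err) < 0))
})

test_that("degenerate geometry raises a geometry error", {
  expect_error(buildLVMesh(geometry = list(a_endo = 30, a_epi = 25,
                                           c_endo = 50, c_epi = 55,
                                           z_base = 25, z_apex = -42)),
               "geometry error")
})

test_that("local frames are right-handed orthonormal triads", {
  mesh <- buildLVMesh(divisions = c(12, 4, 2))
  fr <- localFrames(mesh)
  dot <- function(a, b) rowSums(a * b)
  expect_lt(max(abs(dot(fr@circumferential, fr@radial))), 1e-10)
  expect_lt(max(abs(dot(fr@circumferential, fr@longitudinal))), 1e-10)
  expect_lt(max(abs(dot(fr@radial, fr@longitudinal))), 1e-10)
  expect_lt(max(abs(dot(fr@radial, fr@radial) - 1)), 1e-10)
  cross <- cbind(
    fr@longitudinal[, 2] * fr@radial[, 3] - fr@longitudinal[, 3] * fr@radial[, 2],
    fr@longitudinal[, 3] * fr@radial[, 1] - fr@longitudinal[, 1] * fr@radial[, 3],
    fr@longitudinal[, 1] * fr@radial[, 2] - fr@longitudinal[, 2] * fr@radial[, 1])
  expect_lt(max(abs(cross - fr@circumferential)), 1e-10)
})

test_that("radial frame points outward on the equator", {
  mesh <- buildLVMesh(divisions = c(16, 8, 2))
  fr <- localFrames(mesh)
  quad <- warpstrain:::.cppQuadrature(mesh@nodes, mesh@elements)
  # quadrature point closest to the +x equatorial midwall
  i <- which.min((quad$points[, 1] - 30)^2 + quad$points[, 2]^2 +
                 quad$points[, 3]^2)
  expect_gt(fr@radial[i, 1], 0.95)
  expect_lt(abs(fr@radial[i, 2]), 0.3)
})

test_that("circumferential vectors turn once around a slice", {
  mesh <- buildLVMesh(divisions = c(16, 4, 1))
  fr <- localFrames(mesh)
  quad <- warpstrain:::.cppQuadrature(mesh@nodes, mesh@elements)
  ring <- which(rep(mesh@slice_index, each = 8) == 2)
  ang <- atan2(quad$points[ring, 2], quad$points[ring, 1])
  ord <- ring[order(ang)]
  v <- fr@circumferential[ord, 1:2]
  turn <- sum(asin(pmin(1, pmax(-1,
    v[, 1] * rbind(v[-1, ], v[1, ])[, 2] -
    v[, 2] * rbind(v[-1, ], v[1, ])[, 1]))))
  expect_equal(turn, 2 * pi, tolerance = 0.05)
})

test_that("fiber inclination reproduces the transmural triple", {
  angles <- c(-82, 0, 80)
  expect_equal(warpstrain:::.inclinationAngle(angles, 0), -82)
  expect_equal(warpstrain:::.inclinationAngle(angles, 0.5), 0)
  expect_equal(warpstrain:::.inclinationAngle(angles, 1), 80)
  expect_equal(warpstrain:::.inclinationAngle(angles, 0.25), -41)
  # monotone through the wall for the baseline triple
  d <- seq(0, 1, length.out = 41)
  expect_true(all(diff(warpstrain:::.inclinationAngle(angles, d)) > 0))
})

test_that("zero inclination angles give the circumferential direction", {
  mesh <- buildLVMesh(divisions = c(8, 2, 1))
  fr <- localFrames(mesh)
  fib <- assignFibers(mesh, c(0, 0, 0), fr)
  expect_lt(max(abs(fib@vectors - fr@circumferential)), 1e-12)
})

test_that("fiber vectors are unit length and vary with depth", {
  mesh <- buildLVMesh(divisions = c(12, 4, 3))
  fib <- assignFibers(mesh, c(-82, 0, 80))
  expect_lt(max(abs(sqrt(rowSums(fib@vectors^2)) - 1)), 1e-10)
  # epicardial-band and endocardial-band fibers differ strongly
  epi <- mesh@wall_depth < 0.2
  endo <- mesh@wall_depth > 0.8
  align <- mean(rowSums(fib@vectors[epi, ][1:10, ] * fib@vectors[endo, ][1:10, ]))
  expect_lt(align, 0.5)
})

test_that("fiber perturbation scales and rounds to printed triples", {
  expect_identical(perturbFiberAngles(c(-82, 0, 80), 0.05), c(-86, 0, 84))
  expect_identical(perturbFiberAngles(c(-82, 0, 80), -0.05), c(-78, 0, 76))
  expect_identical(perturbFiberAngles(c(-82, 0, 80), 0), c(-82, 0, 80))
  expect_error(perturbFiberAngles(c(-82, 0, 80), 1.2), "fraction")
})

test_that("regions partition each slice equally and rotate cyclically", {
  mesh <- buildLVMesh(divisions = c(16, 4, 1))
  tab <- table(mesh@region[mesh@slice_index == 1])
  expect_equal(as.vector(tab), rep(4L, 4))
  expect_setequal(names(tab), c("anterior", "lateral", "posterior", "septal"))
  for (s in unique(mesh@slice_index))
    expect_setequal(unique(mesh@region[mesh@slice_index == s]),
                    c("anterior", "lateral", "posterior", "septal"))
  # rotating the mesh by 90 degrees about z permutes labels cyclically
  rot <- mesh
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot@nodes <- mesh@nodes %*% t(R)
  relabeled <- labelRegions(rot)
  cyc <- c(lateral = "anterior", anterior = "septal", septal = "posterior",
           posterior = "lateral")
  expect_identical(relabeled, unname(cyc[mesh@region]))
})

test_that("region labeling is invariant to mesh resolution", {
  coarse <- buildLVMesh(divisions = c(8, 2, 1))
  fine <- buildLVMesh(divisions = c(16, 2, 1))
  # element centroid angle determines the label under either resolution
  ang <- function(m) atan2(
    rowMeans(matrix(m@nodes[t(m@elements), 2], ncol = 8, byrow = TRUE)),
    rowMeans(matrix(m@nodes[t(m@elements), 1], ncol = 8, byrow = TRUE)))
  sector <- function(a) c("lateral", "anterior", "septal",
                          "posterior")[1 + ((floor((a * 180 / pi + 45) / 90)) %% 4)]
  expect_identical(coarse@region, sector(ang(coarse)))
  expect_identical(fine@region, sector(ang(fine)))
})

test_that("VTU export writes a well-formed file", {
  mesh <- buildLVMesh(divisions = c(8, 2, 1))
  fib <- assignFibers(mesh)
  path <- tempfile(fileext = ".vtu")
  exportMeshVTK(mesh, path, fib)
  txt <- readLines(path)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl("NumberOfCells=\"16\"", txt)))
  unlink(path)
})
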