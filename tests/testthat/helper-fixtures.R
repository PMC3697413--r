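# Shared fixtures, all built in code.

# Single unit-cube element in standard hex ordering, fibers along x.
unitCubeMesh <- function() {
  nodes <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                    0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1),
                  ncol = 3, byrow = TRUE)
  new("HexMesh", nodes = nodes, elements = matrix(1:8, 1, 8),
      wall_depth = rep(0.5, 8), region = "anterior", slice_index = 1L,
      geometry = list())
}

xFiber <- function(nqp = 8L) {
  new("FiberField", angles = c(0, 0, 0),
      vectors = matrix(rep(c(1, 0, 0), each = nqp), ncol = 3))
}

# Symmetry constraints for the unit cube: coordinate planes fixed in their
# normal direction.
cubeSymmetryConstraints <- function(mesh) {
  rbind(data.frame(node = which(mesh@nodes[, 1] == 0), dof = 1L),
        data.frame(node = which(mesh@nodes[, 2] == 0), dof = 2L),
        data.frame(node = which(mesh@nodes[, 3] == 0), dof = 3L))
}

# Small smooth synthetic volume (sum of Gaussian blobs), deterministic.
smoothTestImage <- function(dims = c(16L, 16L, 12L), spacing = c(2, 2, 3)) {
  origin <- -spacing * (dims - 1) / 2
  xs <- origin[1] + spacing[1] * (0:(dims[1] - 1))
  ys <- origin[2] + spacing[2] * (0:(dims[2] - 1))
  zs <- origin[3] + spacing[3] * (0:(dims[3] - 1))
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- 50 * exp(-((g$x - 3)^2 + g$y^2 + g$z^2) / 200) +
       30 * exp(-((g$x + 5)^2 + (g$y - 4)^2 + (g$z + 2)^2) / 150)
  Image3D(array(v, dims), spacing = spacing, origin = origin)
}

# A small phantom spec for cheap end-to-end style tests (coarse grid).
smallPhantomSpec <- function(...) {
  args <- utils::modifyList(list(dims = c(32L, 32L, 12L),
                                 spacing = c(6, 6, 9.5), blur_fwhm = 8),
                            list(...))
  do.call(PhantomSpec, args)
}

randomRotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

defaultPhantomMeshDivisions <- c(24L, 6L, 3L)
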