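# Truncated prolate-spheroid LV wall: endo and epi surfaces
#   r_s(z) = a_s * sqrt(1 - (z/c_s)^2),  z in [z_apex, z_base]
# meshed with 8-node hexahedra (open apex and base: a tube topology).

.wallRadius <- function(geom, z, depth) {
  re <- geom$a_epi * sqrt(pmax(0, 1 - (z / geom$c_epi)^2))
  ri <- geom$a_endo * sqrt(pmax(0, 1 - (z / geom$c_endo)^2))
  (1 - depth) * re + depth * ri
}

.wallRadiusDz <- function(geom, z, depth) {
  dre <- -geom$a_epi * z / (geom$c_epi^2 * sqrt(pmax(1e-12, 1 - (z / geom$c_epi)^2)))
  dri <- -geom$a_endo * z / (geom$c_endo^2 * sqrt(pmax(1e-12, 1 - (z / geom$c_endo)^2)))
  (1 - depth) * dre + depth * dri
}

# Transmural depth of arbitrary points: 0 at epicardium, 1 at endocardium.
.wallDepthAt <- function(geom, pts) {
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  re <- .wallRadius(geom, pts[, 3], 0)
  ri <- .wallRadius(geom, pts[, 3], 1)
  pmin(1, pmax(0, (re - r) / pmax(re - ri, 1e-9)))
}

#' Build a truncated prolate-spheroid LV mesh
#'
#' Generates a closed-circumference, open-apex hexahedral mesh of the left
#' ventricular wall between confocal-like endo- and epicardial ellipsoid
#' surfaces, with per-quadrature-point wall depth, per-element anatomical
#' region labels and short-axis band indices.
#'
#' @param geometry list with \code{a_endo}, \code{a_epi} (equatorial radii,
#'   mm), \code{c_endo}, \code{c_epi} (long semi-axes, mm), \code{z_base},
#'   \code{z_apex} (truncation planes, mm). Defaults mirror
#'   [PhantomSpec()].
#' @param divisions integer(3): circumferential, longitudinal, transmural
#'   element counts; must be at least (4, 2, 1).
#' @return A [HexMesh-class].
#' @examples
#' mesh <- buildLVMesh(divisions = c(16, 8, 3))
#' nrow(mesh@nodes)      # 16 * 9 * 4
#' nrow(mesh@elements)   # 16 * 8 * 3
#' @export
buildLVMesh <- function(geometry = list(a_endo = 25, a_epi = 35, c_endo = 50,
                                        c_epi = 55, z_base = 25, z_apex = -42),
                        divisions = c(24L, 6L, 3L)) {
  geom <- geometry
  if (geom$a_epi <= geom$a_endo || geom$a_endo <= 0)
    stop("geometry error: wall thickness must be positive (a_epi > a_endo > 0)")
  if (abs(geom$z_base) >= geom$c_endo || abs(geom$z_apex) >= geom$c_endo)
    stop("geometry error: truncation planes must cut the endocardial surface")
  nc <- as.integer(divisions[1]); nl <- as.integer(divisions[2])
  nt <- as.integer(divisions[3])
  if (nc < 4L || nl < 2L || nt < 1L)
    stop("divisions must be at least (4, 2, 1)")

  theta <- 2 * pi * (0:(nc - 1)) / nc
  zs <- seq(geom$z_apex, geom$z_base, length.out = nl + 1)
  depths <- seq(1, 0, length.out = nt + 1)  # transmural layer 0 = endo

  nid <- function(ic, il, it) {
    ic <- (ic - 1L) %% nc + 1L
    ic + nc * (il - 1L) + nc * (nl + 1L) * (it - 1L)
  }
  nodes <- matrix(0, nc * (nl + 1) * (nt + 1), 3)
  for (it in 1:(nt + 1))
    for (il in 1:(nl + 1)) {
      r <- .wallRadius(geom, zs[il], depths[it])
      ids <- nid(1:nc, il, it)
      nodes[ids, ] <- cbind(r * cos(theta), r * sin(theta), zs[il])
    }

  elems <- matrix(0L, nc * nl * nt, 8)
  e <- 0L
  for (it in 1:nt)
    for (il in 1:nl)
      for (ic in 1:nc) {
        e <- e + 1L
        # local axes: xi = circumferential, eta = longitudinal,
        # zeta = transmural endo -> epi (right-handed, det J > 0)
        elems[e, ] <- c(nid(ic, il, it), nid(ic + 1L, il, it),
                        nid(ic + 1L, il + 1L, it), nid(ic, il + 1L, it),
                        nid(ic, il, it + 1L), nid(ic + 1L, il, it + 1L),
                        nid(ic + 1L, il + 1L, it + 1L),
                        nid(ic, il + 1L, it + 1L))
      }

  quad <- .cppQuadrature(nodes, elems)
  wall_depth <- .wallDepthAt(geom, quad$points)

  # slice bands: 1 at the base
  il_of <- rep(rep(1:nl, each = nc), times = nt)
  slice_index <- as.integer(nl + 1L - il_of)

  mesh <- new("HexMesh", nodes = nodes, elements = elems,
              wall_depth = wall_depth, region = rep("unset", nrow(elems)),
              slice_index = slice_index, geometry = geom)
  mesh@region <- labelRegions(mesh)
  mesh
}

#' Label anatomical regions
#'
#' Partitions the elements of every short-axis band into four equal 90-degree
#' circumferential quadrants by element centroid angle. Convention:
#' anterior = +y, lateral = +x, posterior = -y, septal = -x quadrant,
#' quadrants centered on the axes.
#'
#' @param mesh a [HexMesh-class].
#' @return character vector of per-element labels.
#' @export
labelRegions <- function(mesh) {
  cx <- rowMeans(matrix(mesh@nodes[t(mesh@elements), 1], ncol = 8,
                        byrow = TRUE))
  cy <- rowMeans(matrix(mesh@nodes[t(mesh@elements), 2], ncol = 8,
                        byrow = TRUE))
  ang <- atan2(cy, cx) * 180 / pi          # (-180, 180]
  lab <- rep("lateral", length(ang))
  lab[ang >= 45 & ang < 135] <- "anterior"
  lab[ang >= 135 | ang < -135] <- "septal"
  lab[ang >= -135 & ang < -45] <- "posterior"
  lab
}

#' Local cardiac coordinate frames at quadrature points
#'
#' Radial is the outward wall normal of the reference ellipsoid surface at
#' the point's transmural depth; longitudinal is the apex-to-base tangent
#' (+z projected onto the wall-tangent plane); circumferential completes the
#' right-handed triad as longitudinal x radial.
#'
#' @param mesh a [HexMesh-class].
#' @return A [LocalFrame-class].
#' @export
localFrames <- function(mesh) {
  quad <- .cppQuadrature(mesh@nodes, mesh@elements)
  pts <- quad$points
  geom <- mesh@geometry
  d <- mesh@wall_depth
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ct <- pts[, 1] / r
  st <- pts[, 2] / r
  drdz <- .wallRadiusDz(geom, pts[, 3], d)
  # outward normal of surface r - r_d(z) = 0
  rad <- cbind(ct, st, -drdz)
  rad <- rad / sqrt(rowSums(rad^2))
  zhat <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3)
  lon <- zhat - rad * rowSums(zhat * rad)
  lon <- lon / sqrt(rowSums(lon^2))
  circ <- cbind(lon[, 2] * rad[, 3] - lon[, 3] * rad[, 2],
                lon[, 3] * rad[, 1] - lon[, 1] * rad[, 3],
                lon[, 1] * rad[, 2] - lon[, 2] * rad[, 1])
  circ <- circ / sqrt(rowSums(circ^2))
  new("LocalFrame", circumferential = circ, radial = rad, longitudinal = lon)
}

.inclinationAngle <- function(angles, depth) {
  # piecewise linear through (0, epi), (0.5, mid), (1, endo)
  ifelse(depth <= 0.5,
         angles[1] + (angles[2] - angles[1]) * depth / 0.5,
         angles[2] + (angles[3] - angles[2]) * (depth - 0.5) / 0.5)
}

#' Assign a transmural fiber field
#'
#' The inclination (helix) angle, measured from the circumferential
#' direction in the wall-tangent plane and positive toward the base, varies
#' piecewise-linearly in wall depth through the (epicardial, midwall,
#' endocardial) triple. The fiber vector is the circumferential frame vector
#' rotated about the radial direction by the inclination angle.
#'
#' @param mesh a [HexMesh-class].
#' @param angles numeric(3) inclination angles (epi, mid, endo), degrees.
#' @param frames optional precomputed [LocalFrame-class].
#' @return A [FiberField-class].
#' @examples
#' mesh <- buildLVMesh(divisions = c(8, 2, 1))
#' fib <- assignFibers(mesh, c(-82, 0, 80))
#' @export
assignFibers <- function(mesh, angles = c(-82, 0, 80), frames = NULL) {
  if (any(!is.finite(angles)) || length(angles) != 3L)
    stop("angles must be a finite (epi, mid, endo) triple")
  if (is.null(frames)) frames <- localFrames(mesh)
  a <- .inclinationAngle(angles, mesh@wall_depth) * pi / 180
  vec <- frames@circumferential * cos(a) + frames@longitudinal * sin(a)
  vec <- vec / sqrt(rowSums(vec^2))
  new("FiberField", angles = as.numeric(angles), vectors = vec)
}

#' Perturb a fiber inclination-angle triple
#'
#' Scales each angle by (1 + fraction) and rounds to the nearest integer
#' degree, as used in the fiber-sensitivity studies.
#'
#' @param angles numeric(3) (epi, mid, endo), degrees.
#' @param fraction signed real, |fraction| < 1.
#' @return numeric(3) perturbed triple.
#' @examples
#' perturbFiberAngles(c(-82, 0, 80), 0.05)   # -86  0  84
#' perturbFiberAngles(c(-82, 0, 80), -0.05)  # -78  0  76
#' @export
perturbFiberAngles <- function(angles, fraction) {
  if (abs(fraction) >= 1) stop("|fraction| must be < 1")
  round(angles * (1 + fraction))
}

#' Analytic wall volume of the truncated shell
#'
#' @param geometry geometry list as in [buildLVMesh()].
#' @return volume in mm^3.
#' @export
analyticWallVolume <- function(geometry) {
  g <- geometry
  f <- function(a, c, z) pi * a^2 * (z - z^3 / (3 * c^2))
  (f(g$a_epi, g$c_epi, g$z_base) - f(g$a_epi, g$c_epi, g$z_apex)) -
    (f(g$a_endo, g$c_endo, g$z_base) - f(g$a_endo, g$c_endo, g$z_apex))
}

#' Quadrature-rule wall volume of a mesh
#'
#' @param mesh a [HexMesh-class].
#' @return volume in mm^3 (sum of Gauss weights).
#' @export
meshVolume <- function(mesh) {
  sum(.cppQuadrature(mesh@nodes, mesh@elements)$weights)
}

#' Basal boundary constraints
#'
#' All basal-ring nodes are fixed longitudinally; two basal nodes (at 0 and
#' 90 degrees) are additionally pinned in-plane to remove the remaining
#' rigid translation and rotation about the long axis.
#'
#' @param mesh a [HexMesh-class].
#' @return data.frame with columns \code{node} and \code{dof} (1 = x, 2 = y,
#'   3 = z).
#' @export
basalConstraints <- function(mesh) {
  zmax <- max(mesh@nodes[, 3])
  basal <- which(mesh@nodes[, 3] > zmax - 1e-6)
  cons <- data.frame(node = basal, dof = 3L)
  ang <- atan2(mesh@nodes[basal, 2], mesh@nodes[basal, 1])
  p1 <- basal[which.min(abs(ang))]          # near theta = 0
  p2 <- basal[which.min(abs(ang - pi / 2))] # near theta = 90 deg
  cons <- rbind(cons,
                data.frame(node = c(p1, p1, p2, p2), dof = c(1L, 2L, 1L, 2L)))
  unique(cons)
}

#' Export a mesh to VTK (.vtu, ASCII)
#'
#' Writes an unstructured-grid file with region, slice band and mean wall
#' depth as cell data, and optionally mean fiber vectors per element.
#'
#' @param mesh a [HexMesh-class].
#' @param path output path (.vtu).
#' @param fibers optional [FiberField-class].
#' @return Invisibly, \code{path}.
#' @export
exportMeshVTK <- function(mesh, path, fibers = NULL) {
  nn <- nrow(mesh@nodes); ne <- nrow(mesh@elements)
  qpmean <- function(x) rowMeans(matrix(x, ncol = 8, byrow = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne)
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(apply(mesh@nodes, 1, paste, collapse = " "),
                   collapse = "\n"), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(apply(mesh@elements - 1L, 1, paste, collapse = " "),
                   collapse = "\n"), con)
  w('</DataArray><DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(ne) * 8L, collapse = " "), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(12L, ne), collapse = " "), con)
  w('</DataArray></Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  writeLines(paste(as.integer(factor(mesh@region,
    levels = c("anterior", "lateral", "posterior", "septal"))),
    collapse = " "), con)
  w('</DataArray><DataArray type="Int32" Name="slice" format="ascii">')
  writeLines(paste(mesh@slice_index, collapse = " "), con)
  w('</DataArray><DataArray type="Float64" Name="wall_depth" format="ascii">')
  writeLines(paste(qpmean(mesh@wall_depth), collapse = " "), con)
  if (!is.null(fibers)) {
    w('</DataArray><DataArray type="Float64" Name="fiber" NumberOfComponents="3" format="ascii">')
    fm <- cbind(qpmean(fibers@vectors[, 1]), qpmean(fibers@vectors[, 2]),
                qpmean(fibers@vectors[, 3]))
    writeLines(paste(apply(fm, 1, paste, collapse = " "), collapse = "\n"),
               con)
  }
  w('</DataArray></CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
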