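# Synthetic LV phantom: analytic systole (endocardial circumferential
# shortening with incompressible in-plane thickening, base-to-apex twist)
# rendered into PET-like template/target volumes with analytic ground-truth
# deformation gradients.

.phantomGeometry <- function(spec) {
  list(a_endo = spec@a_endo, a_epi = spec@a_epi, c_endo = spec@c_endo,
       c_epi = spec@c_epi, z_base = spec@z_base, z_apex = spec@z_apex)
}

# shortening fraction and twist as functions of z (0 at base, max at apex)
.axialFrac <- function(spec, z) {
  pmin(1, pmax(0, (spec@z_base - z) / (spec@z_base - spec@z_apex)))
}
.shortenAt <- function(spec, z) {
  spec@circ_shorten * (1 + spec@shorten_apex_gain * .axialFrac(spec, z))
}

#' Analytic systolic deformation map of the phantom
#'
#' Maps reference points to their end-systolic positions and returns the
#' analytic deformation gradient. Within the wall the in-plane map is
#' exactly area-preserving (det F = 1): the endocardial radius shrinks by
#' the local shortening fraction and the wall thickens to conserve
#' cross-sectional area; a twist about the long axis grows linearly from
#' base to apex. Inside the blood pool the radial map is linear; the map is
#' continuous and invertible.
#'
#' @param points n x 3 reference world coordinates, mm.
#' @param spec a [PhantomSpec-class].
#' @return list with \code{mapped} (n x 3) and \code{F} (n x 9,
#'   column-major flattened 3 x 3).
#' @export
analyticDeformation <- function(points, spec) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  r <- sqrt(x^2 + y^2)
  geom <- .phantomGeometry(spec)
  dz <- spec@z_base - spec@z_apex
  s <- .shortenAt(spec, z)
  ds_dz <- ifelse(z <= spec@z_base & z >= spec@z_apex,
                  -spec@circ_shorten * spec@shorten_apex_gain / dz, 0)
  re <- geom$a_endo * sqrt(pmax(0, 1 - (z / geom$c_endo)^2))
  dre2_dz <- -2 * geom$a_endo^2 * z / geom$c_endo^2
  # q(z) = r_endo^2 (2s - s^2); wall branch rho = sqrt(r^2 - q)
  q <- re^2 * (2 * s - s^2)
  dq_dz <- dre2_dz * (2 * s - s^2) + re^2 * (2 - 2 * s) * ds_dz
  wall <- r >= re & is.finite(r)
  rho <- ifelse(wall, sqrt(pmax(r^2 - q, 1e-12)), r * (1 - s))
  drho_dr <- ifelse(wall, r / rho, 1 - s)
  drho_dz <- ifelse(wall, -dq_dz / (2 * rho), -r * ds_dz)

  tw <- (spec@twist_deg * pi / 180) * .axialFrac(spec, z)
  dtw_dz <- ifelse(z <= spec@z_base & z >= spec@z_apex,
                   -(spec@twist_deg * pi / 180) / dz, 0)
  theta <- atan2(y, x)
  phi <- theta + tw
  cp <- cos(phi); sp <- sin(phi)
  safe_r <- pmax(r, 1e-12)
  dr_dx <- x / safe_r; dr_dy <- y / safe_r
  dth_dx <- -y / safe_r^2; dth_dy <- x / safe_r^2

  mapped <- unname(cbind(rho * cp, rho * sp, z))
  F <- matrix(0, n, 9)
  # column-major flattening: F[, i + 3*(J-1)] = dx'_i/dX_J
  F[, 1] <- drho_dr * cp * dr_dx - rho * sp * dth_dx  # dx'/dx
  F[, 2] <- drho_dr * sp * dr_dx + rho * cp * dth_dx  # dy'/dx
  F[, 3] <- 0
  F[, 4] <- drho_dr * cp * dr_dy - rho * sp * dth_dy  # dx'/dy
  F[, 5] <- drho_dr * sp * dr_dy + rho * cp * dth_dy  # dy'/dy
  F[, 6] <- 0
  F[, 7] <- drho_dz * cp - rho * sp * dtw_dz          # dx'/dz
  F[, 8] <- drho_dz * sp + rho * cp * dtw_dz          # dy'/dz
  F[, 9] <- 1
  # on-axis points: the map is the identity scaled in-plane
  axis <- r < 1e-9
  if (any(axis)) {
    F[axis, ] <- 0
    F[axis, 1] <- F[axis, 5] <- 1 - s[axis]
    F[axis, 9] <- 1
    mapped[axis, 1:2] <- 0
  }
  list(mapped = mapped, F = F)
}

# Inverse of the radial part of the map, for rendering the deformed wall:
# given deformed in-plane radius rho at height z, recover the reference r.
.inverseRadius <- function(spec, rho, z) {
  geom <- .phantomGeometry(spec)
  s <- .shortenAt(spec, z)
  re <- geom$a_endo * sqrt(pmax(0, 1 - (z / geom$c_endo)^2))
  q <- re^2 * (2 * s - s^2)
  rho_endo <- re * (1 - s)
  ifelse(rho >= rho_endo, sqrt(pmax(rho^2 + q, 0)), rho / (1 - s))
}

.wallIndicator <- function(spec, x, y, z, deformed = FALSE) {
  geom <- .phantomGeometry(spec)
  r <- sqrt(x^2 + y^2)
  if (deformed) r <- .inverseRadius(spec, r, z)
  re <- geom$a_epi * sqrt(pmax(0, 1 - (z / geom$c_epi)^2))
  ri <- geom$a_endo * sqrt(pmax(0, 1 - (z / geom$c_endo)^2))
  in_z <- z >= spec@z_apex & z <= spec@z_base
  as.numeric(in_z & r >= ri & r <= re)
}

# Periodic separable Gaussian blur via FFT.
.gaussBlur <- function(vol, sigma_vox) {
  d <- dim(vol)
  kern1 <- function(n, s) {
    if (s <= 0) return(c(1, rep(0, n - 1)))
    half <- seq(0, floor(n / 2))
    g <- exp(-0.5 * (half / s)^2)
    k <- numeric(n)
    k[1 + half] <- g
    neg <- seq_len(ceiling(n / 2) - 1)
    k[n + 1 - neg] <- exp(-0.5 * (neg / s)^2)
    k / sum(k)
  }
  K <- outer(outer(stats::fft(kern1(d[1], sigma_vox[1])),
                   stats::fft(kern1(d[2], sigma_vox[2]))),
             stats::fft(kern1(d[3], sigma_vox[3])))
  dim(K) <- d
  Re(stats::fft(stats::fft(vol) * K, inverse = TRUE)) / prod(d)
}

#' Render a phantom image volume
#'
#' Indicator of the (optionally deformed) wall region times the wall
#' intensity plus background, convolved with an isotropic Gaussian of the
#' given FWHM (partial-volume emulation). Deterministic given the spec.
#'
#' @param spec a [PhantomSpec-class].
#' @param use_deformed render the end-systolic (deformed) wall.
#' @return An [Image3D-class], centered on the ellipsoid origin.
#' @export
renderImage <- function(spec, use_deformed = FALSE) {
  d <- spec@dims
  origin <- -spec@spacing * (d - 1) / 2
  xs <- origin[1] + spec@spacing[1] * (0:(d[1] - 1))
  ys <- origin[2] + spec@spacing[2] * (0:(d[2] - 1))
  zs <- origin[3] + spec@spacing[3] * (0:(d[3] - 1))
  g <- expand.grid(x = xs, y = ys, z = zs)
  ind <- .wallIndicator(spec, g$x, g$y, g$z, deformed = use_deformed)
  vol <- array(spec@background_intensity +
                 (spec@wall_intensity - spec@background_intensity) * ind, d)
  if (spec@blur_fwhm > 0) {
    sigma <- spec@blur_fwhm / (2 * sqrt(2 * log(2)))
    vol <- .gaussBlur(vol, sigma / spec@spacing)
  }
  Image3D(vol, spacing = spec@spacing, origin = origin)
}

#' Default registration mesh for a phantom
#'
#' @param spec a [PhantomSpec-class].
#' @param divisions passed to [buildLVMesh()].
#' @return A [HexMesh-class] built on the phantom's template geometry.
#' @export
phantomMesh <- function(spec, divisions = c(24L, 6L, 3L)) {
  buildLVMesh(.phantomGeometry(spec), divisions)
}

#' Ground-truth strain table of the analytic map
#'
#' Green-Lagrange circumferential and radial strains of the analytic
#' deformation, evaluated at the mesh quadrature points, projected onto the
#' reference cardiac frames and sampled on the standard region-by-depth
#' layout.
#'
#' @param spec a [PhantomSpec-class].
#' @param mesh a [HexMesh-class] (defaults to [phantomMesh()]).
#' @param frames optional [LocalFrame-class].
#' @param slices short-axis bands to sample; defaults to the interior bands
#'   (basal and apical bands excluded).
#' @return strain sample table (data.frame).
#' @export
phantomTruth <- function(spec, mesh = phantomMesh(spec), frames = NULL,
                         slices = NULL) {
  if (is.null(frames)) frames <- localFrames(mesh)
  quad <- .cppQuadrature(mesh@nodes, mesh@elements)
  def <- analyticDeformation(quad$points, spec)
  strains <- projectedStrains(def$F, frames)
  if (is.null(slices)) slices <- .interiorSlices(mesh)
  sampleHarpGrid(mesh, strains, slices = slices)
}

.interiorSlices <- function(mesh) {
  s <- sort(unique(mesh@slice_index))
  if (length(s) > 2L) s[-c(1L, length(s))] else s
}

#' Generate a template/target phantom pair with ground truth
#'
#' @param spec a [PhantomSpec-class].
#' @param divisions mesh divisions for the truth layout.
#' @return list with \code{template}, \code{target} ([Image3D-class]),
#'   \code{truth} (strain sample table), \code{mesh}, \code{frames}.
#' @export
makePhantomPair <- function(spec = PhantomSpec(), divisions = c(24L, 6L, 3L)) {
  mesh <- phantomMesh(spec, divisions)
  frames <- localFrames(mesh)
  list(template = renderImage(spec, use_deformed = FALSE),
       target = renderImage(spec, use_deformed = TRUE),
       truth = phantomTruth(spec, mesh, frames),
       mesh = mesh, frames = frames)
}
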