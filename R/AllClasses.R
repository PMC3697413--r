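#' @import methods
#' @importFrom stats sd rnorm cor t.test lm coef quantile
#' @importFrom utils write.csv read.csv
#' @useDynLib warpstrain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 3D scalar image volume
#'
#' A scalar voxel grid with per-axis spacing and a world origin. The world
#' position of voxel \code{(i, j, k)} (1-based) is
#' \code{origin + (c(i, j, k) - 1) * spacing}; i.e. coordinates are
#' voxel-center based and axis-aligned, in mm.
#'
#' @slot voxels 3D numeric array, arbitrary intensity units.
#' @slot spacing numeric(3), voxel size per axis, mm (all > 0).
#' @slot origin numeric(3), world position of the center of voxel (1,1,1), mm.
#' @export
setClass("Image3D",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L) msg <- c(msg, "voxels must be a 3D array")
    else if (any(d < 2L)) msg <- c(msg, "each image dimension must be >= 2")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (any(!is.finite(object@voxels)))
      msg <- c(msg, "intensities must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an Image3D
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of the first voxel center, mm.
#' @return An [Image3D-class] object.
#' @examples
#' img <- Image3D(array(0, c(4, 4, 4)), spacing = c(1.5, 1.5, 3.5))
#' @export
Image3D <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- array(as.numeric(voxels), dim(voxels)) # strip classes/attributes
  new("Image3D", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

setMethod("show", "Image3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Image3D: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(object@voxels), max(object@voxels), mean(object@voxels)))
})

#' Additive Gaussian noise specification
#'
#' Defines the noise level through the signal-to-noise ratio
#' SNR = sigma_i / sigma_n, where sigma_i is the standard deviation of the
#' image intensities over the whole volume and sigma_n the standard
#' deviation of the zero-mean Gaussian noise field.
#'
#' @slot snr positive real, dimensionless.
#' @slot seed integer seed for reproducible noise.
#' @export
setClass("NoiseSpec",
  representation(snr = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@snr) != 1L || !is.finite(object@snr) || object@snr <= 0)
      return("snr must be a single positive number")
    TRUE
  }
)

#' @param snr positive signal-to-noise ratio.
#' @param seed integer seed.
#' @rdname NoiseSpec-class
#' @export
NoiseSpec <- function(snr, seed = 1L) {
  new("NoiseSpec", snr = as.numeric(snr), seed = as.integer(seed))
}

setMethod("show", "NoiseSpec", function(object) {
  cat(sprintf("NoiseSpec: SNR = %g, seed = %d\n", object@snr, object@seed))
})

#' Hexahedral left-ventricle mesh
#'
#' Truncated prolate-spheroid wall meshed with 8-node hexahedra. Quadrature
#' uses 2x2x2 Gauss points per element throughout; per-quadrature-point
#' attributes are stored element-major (Gauss point fastest).
#'
#' @slot nodes N x 3 node coordinates, mm.
#' @slot elements E x 8 integer node indices (standard hexahedron ordering).
#' @slot wall_depth length E*8 numeric in [0,1]: 0 = epicardium,
#'   1 = endocardium, at quadrature points.
#' @slot region length E factor/character: anterior, posterior, septal,
#'   lateral.
#' @slot slice_index length E integer short-axis band (1 = base).
#' @slot geometry list of the generating surface parameters (radii, lengths).
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elements = "matrix", wall_depth = "numeric",
                 region = "character", slice_index = "integer",
                 geometry = "list"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be N x 3")
    if (ncol(object@elements) != 8L) msg <- c(msg, "elements must be E x 8")
    if (any(object@elements < 1L) || any(object@elements > nrow(object@nodes)))
      msg <- c(msg, "element node indices out of range")
    if (length(object@wall_depth) != nrow(object@elements) * 8L)
      msg <- c(msg, "wall_depth must have one value per quadrature point")
    if (any(object@wall_depth < -1e-9) || any(object@wall_depth > 1 + 1e-9))
      msg <- c(msg, "wall_depth must lie in [0, 1]")
    if (length(object@region) != nrow(object@elements))
      msg <- c(msg, "region must have one label per element")
    if (length(object@slice_index) != nrow(object@elements))
      msg <- c(msg, "slice_index must have one value per element")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d nodes, %d elements, %d short-axis bands\n",
              nrow(object@nodes), nrow(object@elements),
              length(unique(object@slice_index))))
  cat("  regions:", paste(names(table(object@region)), collapse = ", "), "\n")
})

#' Transmural fiber field
#'
#' Unit myofiber direction at every quadrature point, built from a transmural
#' inclination-angle rule through (epicardial, midwall, endocardial) angles.
#'
#' @slot angles numeric(3): (epi, mid, endo) inclination angles, degrees.
#' @slot vectors (E*8) x 3 unit fiber vectors at quadrature points.
#' @export
setClass("FiberField",
  representation(angles = "numeric", vectors = "matrix"),
  validity = function(object) {
    if (length(object@angles) != 3L)
      return("angles must be (epi, mid, endo)")
    n <- sqrt(rowSums(object@vectors^2))
    if (any(abs(n - 1) > 1e-8))
      return("fiber vectors must be unit length")
    TRUE
  }
)

setMethod("show", "FiberField", function(object) {
  cat(sprintf("FiberField: inclination (epi, mid, endo) = (%g, %g, %g) deg, %d vectors\n",
              object@angles[1], object@angles[2], object@angles[3],
              nrow(object@vectors)))
})

#' Local cardiac coordinate frames
#'
#' Right-handed orthonormal (circumferential, radial, longitudinal) triad at
#' every quadrature point of a mesh.
#'
#' @slot circumferential (E*8) x 3 unit vectors.
#' @slot radial (E*8) x 3 unit vectors (outward wall normal).
#' @slot longitudinal (E*8) x 3 unit vectors (apex-to-base tangent).
#' @export
setClass("LocalFrame",
  representation(circumferential = "matrix", radial = "matrix",
                 longitudinal = "matrix"),
  validity = function(object) {
    n <- nrow(object@circumferential)
    if (nrow(object@radial) != n || nrow(object@longitudinal) != n)
      return("frame components must have equal row counts")
    TRUE
  }
)

setMethod("show", "LocalFrame", function(object) {
  cat(sprintf("LocalFrame: %d quadrature-point triads (circumferential, radial, longitudinal)\n",
              nrow(object@circumferential)))
})

#' Passive material parameters
#'
#' Transversely isotropic hyperelastic myocardium:
#' W = mu/2 (I1_bar - 3) + c1 (exp(c2 (lambda - 1)^2) - 1) for lambda > 1
#' + kappa/2 (ln J)^2, with lambda the fiber stretch. Fiber reinforcement is
#' tension-only.
#'
#' @slot mu matrix (neo-Hookean) stiffness, kPa.
#' @slot c1 fiber exponential scale, kPa.
#' @slot c2 fiber exponential rate, dimensionless.
#' @slot kappa bulk penalty, kPa.
#' @export
setClass("PassiveParams",
  representation(mu = "numeric", c1 = "numeric", c2 = "numeric",
                 kappa = "numeric"),
  validity = function(object) {
    v <- c(object@mu, object@c1, object@c2, object@kappa)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all passive parameters must be positive")
    TRUE
  }
)

#' @param mu,c1,c2,kappa see slots.
#' @rdname PassiveParams-class
#' @export
PassiveParams <- function(mu = 2, c1 = 0.35, c2 = 9, kappa = 100) {
  new("PassiveParams", mu = mu, c1 = c1, c2 = c2, kappa = kappa)
}

setMethod("show", "PassiveParams", function(object) {
  cat(sprintf("PassiveParams: mu = %g kPa, c1 = %g kPa, c2 = %g, kappa = %g kPa\n",
              object@mu, object@c1, object@c2, object@kappa))
})

#' Active contraction parameters (time-varying elastance)
#'
#' Fiber tension T_a = Tmax Ca0^2 / (Ca0^2 + ECa50(l)^2) x activation, with
#' length-dependent calcium sensitivity
#' ECa50(l) = Ca0max / sqrt(exp(B (l - l0)) - 1) and sarcomere length
#' l = lambda * lr. No tension develops at or below l0.
#'
#' @slot Tmax peak isometric tension, kPa.
#' @slot Ca0 intracellular calcium concentration, uM.
#' @slot Ca0max peak intracellular calcium concentration, uM.
#' @slot B shape constant of the tension-sarcomere length relation, 1/um.
#' @slot l0 sarcomere length at which no active tension develops, um.
#' @slot lr unloaded sarcomere length, um.
#' @export
setClass("ActiveParams",
  representation(Tmax = "numeric", Ca0 = "numeric", Ca0max = "numeric",
                 B = "numeric", l0 = "numeric", lr = "numeric"),
  validity = function(object) {
    v <- c(object@Tmax, object@Ca0, object@Ca0max, object@B, object@l0,
           object@lr)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all active parameters must be positive")
    if (object@l0 >= object@lr)
      return("l0 must be smaller than the unloaded length lr")
    TRUE
  }
)

#' @param Tmax,Ca0,Ca0max,B,l0,lr see slots.
#' @rdname ActiveParams-class
#' @export
ActiveParams <- function(Tmax = 135.7, Ca0 = 4.35, Ca0max = 4.35, B = 4.75,
                         l0 = 1.58, lr = 2.04) {
  new("ActiveParams", Tmax = Tmax, Ca0 = Ca0, Ca0max = Ca0max, B = B,
      l0 = l0, lr = lr)
}

setMethod("show", "ActiveParams", function(object) {
  cat(sprintf(
    "ActiveParams: Tmax = %g kPa, Ca0 = %g uM, Ca0max = %g uM, B = %g /um, l0 = %g um, lr = %g um\n",
    object@Tmax, object@Ca0, object@Ca0max, object@B, object@l0, object@lr))
})

#' Penalty schedules for registration
#'
#' The image penalty psi increases linearly over the whole pseudo-time
#' course; the active penalty psi_a increases linearly until \code{knot}
#' (default 2/3 of the analysis) and is then held constant.
#'
#' @slot psi_max image penalty scale at t = 1.
#' @slot psi_a_max active penalty scale at the plateau.
#' @slot knot pseudo-time at which psi_a plateaus, in (0, 1].
#' @export
setClass("PenaltySchedule",
  representation(psi_max = "numeric", psi_a_max = "numeric", knot = "numeric"),
  validity = function(object) {
    if (object@psi_max < 0 || object@psi_a_max < 0)
      return("penalty scales must be non-negative")
    if (object@knot <= 0 || object@knot > 1)
      return("knot must lie in (0, 1]")
    TRUE
  }
)

#' @param psi_max,psi_a_max,knot see slots. Defaults were calibrated once on
#'   the reference phantom (smallest scales achieving at least 80% image
#'   energy reduction) and fixed.
#' @rdname PenaltySchedule-class
#' @export
PenaltySchedule <- function(psi_max = 1e-4, psi_a_max = 0.003, knot = 2 / 3) {
  new("PenaltySchedule", psi_max = psi_max, psi_a_max = psi_a_max, knot = knot)
}

setMethod("show", "PenaltySchedule", function(object) {
  cat(sprintf("PenaltySchedule: psi_max = %g, psi_a_max = %g, knot = %g\n",
              object@psi_max, object@psi_a_max, object@knot))
})

#' Registration result
#'
#' Displacement history over pseudo-time together with the activation (Ct)
#' and image-energy traces.
#'
#' @slot times pseudo-times of the stored steps, in [0, 1].
#' @slot displacements list of N x 3 nodal displacement matrices, mm.
#' @slot ct_trace per-step mean template-target intensity mismatch.
#' @slot energy_trace per-step image energy (at the step's psi).
#' @slot mismatch_trace per-step raw intensity mismatch integral
#'   (image energy at psi = 1), comparable across steps.
#' @slot converged logical per step.
#' @export
setClass("RegistrationResult",
  representation(times = "numeric", displacements = "list",
                 ct_trace = "numeric", energy_trace = "numeric",
                 mismatch_trace = "numeric", converged = "logical"),
  validity = function(object) {
    n <- length(object@times)
    if (length(object@displacements) != n || length(object@ct_trace) != n ||
        length(object@energy_trace) != n || length(object@converged) != n)
      return("trace lengths must match the number of stored steps")
    if (is.unsorted(object@times))
      return("steps must be ordered in pseudo-time")
    TRUE
  }
)

setMethod("show", "RegistrationResult", function(object) {
  n <- length(object@times)
  cat(sprintf("RegistrationResult: %d pseudo-time steps (%d converged)\n",
              n, sum(object@converged)))
  if (n > 0) {
    cat(sprintf("  final max |u| = %.4g mm, Ct = %.4g, mismatch %.4g -> %.4g\n",
                max(abs(object@displacements[[n]])), object@ct_trace[n],
                object@mismatch_trace[1], object@mismatch_trace[n]))
  }
})

#' Synthetic left-ventricle phantom specification
#'
#' Geometry, imaging grid, and analytic systolic deformation parameters of
#' the PET-like phantom. The wall is a truncated prolate spheroid (endo and
#' epi surfaces with equatorial radii \code{a_*} and long semi-axes
#' \code{c_*}, truncated at \code{z_base} and \code{z_apex}). Systole is an
#' in-plane incompressible contraction: the endocardial radius shrinks by
#' \code{circ_shorten} (growing by \code{shorten_apex_gain} toward the apex),
#' wall thickening follows from area preservation, plus a base-to-apex twist.
#'
#' @slot a_endo,a_epi equatorial radii of endo/epi surfaces, mm.
#' @slot c_endo,c_epi long semi-axes of endo/epi surfaces, mm.
#' @slot z_base,z_apex truncation planes, mm (base > apex; ellipsoid centered
#'   at z = 0).
#' @slot dims integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot wall_intensity,background_intensity arbitrary units.
#' @slot blur_fwhm isotropic Gaussian blur FWHM, mm.
#' @slot circ_shorten endocardial circumferential shortening fraction at the
#'   base (dimensionless).
#' @slot shorten_apex_gain relative increase of the shortening fraction from
#'   base to apex.
#' @slot twist_deg base-to-apex twist, degrees.
#' @slot seed integer seed for any stochastic use.
#' @export
setClass("PhantomSpec",
  representation(a_endo = "numeric", a_epi = "numeric", c_endo = "numeric",
                 c_epi = "numeric", z_base = "numeric", z_apex = "numeric",
                 dims = "integer", spacing = "numeric",
                 wall_intensity = "numeric", background_intensity = "numeric",
                 blur_fwhm = "numeric", circ_shorten = "numeric",
                 shorten_apex_gain = "numeric", twist_deg = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!(object@a_epi > object@a_endo && object@a_endo > 0))
      msg <- c(msg, "need a_epi > a_endo > 0")
    if (!(object@c_epi >= object@c_endo && object@c_endo > 0))
      msg <- c(msg, "need c_epi >= c_endo > 0")
    if (object@z_base <= object@z_apex)
      msg <- c(msg, "z_base must exceed z_apex")
    if (any(object@dims[1:2] < 16L))
      msg <- c(msg, "in-plane grid dimensions must be >= 16")
    if (object@blur_fwhm < 0) msg <- c(msg, "blur FWHM must be >= 0")
    if (object@circ_shorten < 0 || object@circ_shorten >= 1)
      msg <- c(msg, "circ_shorten must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' @param a_endo,a_epi,c_endo,c_epi,z_base,z_apex,dims,spacing see slots.
#' @param wall_intensity,background_intensity,blur_fwhm see slots.
#' @param circ_shorten,shorten_apex_gain,twist_deg,seed see slots.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(a_endo = 25, a_epi = 35, c_endo = 50, c_epi = 55,
                        z_base = 25, z_apex = -42,
                        dims = c(64L, 64L, 16L), spacing = c(3, 3, 7),
                        wall_intensity = 100, background_intensity = 10,
                        blur_fwhm = 6, circ_shorten = 0.15,
                        shorten_apex_gain = 0.25, twist_deg = 8, seed = 1L) {
  new("PhantomSpec", a_endo = a_endo, a_epi = a_epi, c_endo = c_endo,
      c_epi = c_epi, z_base = z_base, z_apex = z_apex,
      dims = as.integer(dims), spacing = as.numeric(spacing),
      wall_intensity = wall_intensity,
      background_intensity = background_intensity, blur_fwhm = blur_fwhm,
      circ_shorten = circ_shorten, shorten_apex_gain = shorten_apex_gain,
      twist_deg = twist_deg, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: endo (%g, %g) / epi (%g, %g) mm, z in [%g, %g] mm\n",
    object@a_endo, object@c_endo, object@a_epi, object@c_epi,
    object@z_apex, object@z_base))
  cat(sprintf("  grid %d x %d x %d at (%g, %g, %g) mm, blur FWHM %g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@blur_fwhm))
  cat(sprintf("  systole: shortening %.3g (apex gain %.3g), twist %g deg\n",
              object@circ_shorten, object@shorten_apex_gain,
              object@twist_deg))
})
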