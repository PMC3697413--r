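---
title: "Hyperelastic warping for left-ventricular strain estimation: models, parameters, and design choices"
author: "warpstrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperelastic warping for left-ventricular strain estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gated cardiac PET shows the left-ventricular (LV) wall as a bright,
partial-volume-blurred band between end-diastole (the *template* volume
`T`) and end-systole (the *target* volume `S`). Hyperelastic warping
estimates the systolic deformation by embedding a finite-element model of
the LV wall in the template and letting image-mismatch forces deform it
onto the target, while the model's hyperelastic strain energy regularizes
the map. The deformation map is `x = X + u(X)` with deformation gradient
`F = I + du/dX`; the recovered Green–Lagrange strain `E = (F'F - I)/2`,
projected onto local circumferential and radial directions, is the
clinically interesting output.

The image term is the pointwise squared mismatch `psi/2 (T(X) - S(phi))^2`
integrated over the model; its first variation gives a body force
`psi (T - S) dS/dphi` — mismatch sets the magnitude, the target's intensity
gradient the direction. Because PET intensity alone cannot supply the
global systolic contraction (flat-intensity regions give no force), a
*subject-specific active contraction* acts along the myofiber direction:
a time-varying-elastance fiber tension

    T_a = Tmax * Ca0^2 / (Ca0^2 + ECa50(l)^2) * psi_a * Ct
    ECa50(l) = Ca0max / sqrt(exp(B (l - l0)) - 1),   l = lambda * lr

driven by the mean template–target intensity mismatch `Ct` averaged over
all mesh elements: the model contracts while it is globally misaligned and
stops contracting as registration completes. Constants: `Ca0max = 4.35`
uM, `B = 4.75` /um, `l0 = 1.58` um (zero-tension sarcomere length),
`lr = 2.04` um (unloaded length), `Tmax = 135.7` kPa, `Ca0 = Ca0max` by
default. The elastance formula is used in its square-root form, which is
the form consistent with the time-varying-elastance literature and
preserves the zero-tension property at `l0`.

## Passive material

The wall is transversely isotropic hyperelastic:

    W = mu/2 (I1_bar - 3) + c1 (exp(c2 (lambda - 1)^2) - 1)[lambda > 1]
        + kappa/2 (ln J)^2

with `mu = 2` kPa (neo-Hookean matrix), `c1 = 0.35` kPa, `c2 = 9`
(exponential fiber reinforcement, tension-only so compressed fibers do not
add nonphysical stiffness), and `kappa = 100` kPa (near-incompressibility
penalty — myocardium is nearly incompressible, and a penalty keeps the
solver simple at desk scale). These constants are the standard order of
magnitude for passive myocardium in this constitutive class and are fully
configurable; the registration result is driven far more by the penalty
schedules than by their exact values.

## Discretization and solver

The LV is a truncated prolate-spheroid wall (endo/epi surfaces
`r = a sqrt(1 - (z/c)^2)`, truncated at a basal and an apical plane, open
apex) meshed with 8-node hexahedra and 2x2x2 Gauss quadrature. Default
divisions are 24 (circumferential) x 6 (longitudinal) x 3 (transmural):
straight-edged hexahedra inscribe the curved shell, and 24 circumferential
segments keep the wall-volume discretization error near 1% (16 segments
would already exceed 2%). Wall depth, the local
circumferential/radial/longitudinal triad, and region labels (anterior
+y, lateral +x, posterior -y, septal -x quadrants) are evaluated
analytically from the generating surfaces at each quadrature point, so
they are mesh-resolution independent. The fiber helix angle runs
piecewise-linearly in wall depth through (epi, mid, endo) = (-82, 0, 80)
degrees, the standard cardiac convention (negative epicardial, positive
endocardial).

Equilibrium at each pseudo-time step is solved by Newton iteration with a
sparse tangent and backtracking line search, to a relative residual of
1e-8. The element tangent is assembled from a central finite-difference
linearization of the first Piola stress with respect to `F` at each
quadrature point; in the total-Lagrangian setting this is the exact
consistent tangent up to O(h^2), which preserves quadratic convergence
while keeping the constitutive code in one place. Boundary conditions:
all basal-ring nodes are fixed longitudinally and two basal nodes are
pinned in-plane to remove the remaining rigid modes. The pins locally
disturb the basal band, which is one reason the default strain sampling
uses interior short-axis bands only (the other: clinical HARP analyses are
mid-ventricular).

## Image interpolation: a deliberate two-tier choice

`sampleIntensity()`/`sampleGradient()` default to trilinear interpolation
with its analytic (per-cell) gradient — the natural reading of
voxel-center sampling, and what the basic examples assume. The
*registration functional*, however, defaults to an interpolating C2 cubic
B-spline (Unser recursive prefilter, mirror boundaries): the trilinear
interpolant's gradient jumps across voxel-cell faces, and those kinks make
the image force field non-differentiable — in practice the Newton
iterations fall into small limit cycles around voxel boundaries
(observed stall near relative residuals of 1e-3) and cannot meet the 1e-8
tolerance. With the C2 spline the image energy has an exact second
variation `psi [grad S grad S' - (T - S) hess S]`, which the solver
assembles, restoring quadratic convergence. Both interpolants are exposed
(`interp = "linear"/"cubic"`) and the force/energy consistency oracle is
tested for both. Outside the grid, intensity and gradient are zero: PET
background is air/blood with near-zero counts, and the image force should
vanish where there is no data.

## Penalty schedules and their calibration

The image penalty ramps linearly over the whole pseudo-time course
(`psi = t psi_max`); the active penalty ramps linearly to its plateau at
`t = 2/3` and is then held constant. The two scales are not universal
constants — they balance image units (intensity^2) against stress units —
and were calibrated **once** on the reference phantom as the smallest
values achieving at least 80% image-energy reduction, then fixed as
package defaults (`psi_max = 1e-4`, `psi_a_max = 0.003`): small enough
that the active contraction performs the global alignment and the image
forces only the local refinement, mirroring the "minimum penalty that
provides reasonable alignment" guidance for the active term. Larger image
penalties register this clean phantom on their own, which makes the
active component redundant and defeats the method's design (and the
real-data regime it emulates, where intensity information alone cannot
align the model). Larger active penalties over-contract: the
activation-deformation feedback loop has high gain, and beyond roughly
twice the default it overshoots into oscillation.

**Signed vs absolute mismatch drive.** In its defining form, `Ct` is the
signed per-element mean of `T - S(phi)`; activation is clamped at zero so a
target brighter than the template cannot generate negative fiber tension.
This package drives the activation with the *magnitude* of the mismatch
by default (`ct_absolute = TRUE` in `register()`; the signed reading is
one flag away, and `averageIntensityMismatch()` itself reports the signed
value by default). The reason is a behavior the signed reading forces on
any brightness-conserving image pair: systolic wall thickening raises the
apparent wall intensity (partial-volume "brightening"), so once
registration is good the registered target is locally *brighter* than the
template, `Ct` turns negative, and the clamp switches the active stress
off permanently — the active component then cannot influence any
well-registered end state, contradicting the method's documented
sensitivity to removing it. For image pairs whose template is globally
brighter than the target (the clinical situation motivating the model,
where intensity drops 6-10% from end-diastole to end-systole), the two
readings coincide. Conceptually the activation drive is the amount of residual
misregistration, which the magnitude reading implements directly. The
default pseudo-time discretization is 30 equal steps.

## The synthetic phantom

The phantom emulates a short-axis PET pair: a truncated prolate-spheroid
wall (defaults: endo 25/50 mm, epi 35/55 mm equatorial/long semi-axes,
base at z = +25 mm, apical truncation at -42 mm), wall intensity 100,
background 10 arbitrary units, isotropic Gaussian blur of 6 mm FWHM for
partial-volume effects. Systole is analytic: the endocardial radius
shrinks by 15% at the base, growing by a 25% gain toward the apex (giving
slice-to-slice strain variation), the wall thickens so the in-plane map
is *exactly* area-preserving (det F = 1 across the wall), and an 8-degree
base-to-apex twist adds torsional shear. These magnitudes are
mid-physiologic for human systole (endocardial circumferential strain
about -0.14, radial thickening strain about +0.20). Ground-truth strain
is evaluated from the analytic `F` at the mesh quadrature points, so
truth is exact and grid-independent.

The default grid is 64 x 64 x 16 voxels at 3 x 3 x 7 mm — the same field
of view as the clinical short-axis grids (100 x 100 x 42 at
1.5 x 1.5 x 3.5 mm, available via the spec) with 8x fewer voxels, chosen
so a full registration plus its ablation control runs in minutes on one
CPU. The phantom does **not** emulate: PET noise statistics (the additive
Gaussian model is deliberately the simple one used for sensitivity
studies, not reconstruction noise), attenuation or scatter, perfusion
defects, through-plane tag motion, or inter-subject anatomical
variability. Passing the phantom pipeline therefore demonstrates internal
consistency of the method — that the machinery recovers a known systolic
strain field from PET-like image pairs — not clinical accuracy on real
scans.

## Strain sampling and comparison statistics

Following the tagged-MRI comparison layout, each sampled short-axis band
is partitioned into 4 regions x 3 transmural depths (depth bands [0,1/3),
[1/3,2/3), [2/3,1] from epi to endo), and projected strains are averaged
over the quadrature points of each cell: exactly 12 circumferential and
12 radial values per band. The comparison report gives the squared
Pearson correlation (R^2), the percent root-mean-square error
`sqrt(mean((ref - pred)^2 / ref^2))` (per-entry normalization; the
ratio-of-sums variant is a flag), Bland–Altman bias with 1.96 sd limits
of agreement and the regression slope of differences on means, and a
two-sided paired t-test. Near-zero reference strains (|ref| < 0.01) are
excluded from the %RMSE with a logged count, since the per-entry ratio is
unstable there. Degenerate inputs (identical tables, zero variance)
return NA statistics rather than errors.

## Numerical details and edge cases

- Quadrature: 2x2x2 Gauss everywhere; element Jacobians are checked
  positive at build time and `det F > 0` at every constitutive
  evaluation (violations raise errors carrying the element id).
- Newton: backtracking halves the step until the true residual (with
  re-evaluated image forces) decreases; an absolute residual floor of
  1e-9 recognizes the machine-zero equilibrium of an identical
  template/target pair.
- `ECa50` returns +Inf at or below `l0`, making the tension exactly zero
  there; tension is continuous at `l0` from both sides.
- Noise: sigma_i is the standard deviation over the *whole* volume (no
  foreground mask); template and target are noised independently (seeds
  `seed` and `seed + 1` in the CLI), and `snr >= 1e12` short-circuits to
  exact zero noise.
- Fiber perturbation rounds to integer degrees, matching the printed
  perturbed triples of the sensitivity protocol.
- The apex is open by default (both in the mesh and in the phantom wall);
  a closed apex is a geometry variant, not required by the sampling
  layout, which uses interior bands.

## Problem sizes used in the shipped checks

The end-to-end checks register the default 64 x 64 x 16 phantom on the
24 x 6 x 3 mesh (672 nodes, 432 elements, 2016 dof) over 30 pseudo-time
steps, with an ablated (no active contraction) control run and an
identical-pair fixed-point run; each registration takes a few minutes on
one CPU. Unit oracles (force/energy consistency, stress/energy
consistency, objectivity, patch test vs single-point inversion) run on a
single element or a coarse mesh in seconds.

## Known limitations

- The Gaussian noise model does not represent reconstructed-PET noise;
  conclusions about noise robustness transfer only qualitatively.
- The phantom is axisymmetric, so region-to-region strain variation
  within a slice is absent; R^2 on the phantom is driven by transmural
  and slice-to-slice variation.
- Basal pinning perturbs the basal band; sample interior bands.
- No cavity pressure, no viscoelasticity, no inertial terms; the
  registration is quasi-static in pseudo-time.
- Single target volume (end-diastole to end-systole); multi-frame
  sequential registration is out of scope.
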