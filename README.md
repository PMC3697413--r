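# warpstrain

Finite-element deformable registration (**hyperelastic warping**) of gated
cardiac image volume pairs, for estimating left-ventricular (LV) systolic
strain from PET-like images.

## The problem and who this is for

Gated PET shows the LV wall between end-diastole (the *template* volume
`T`) and end-systole (the *target* `S`), but wall motion and thickening
are only indirect measures of function. Hyperelastic warping recovers the
full 3D deformation map `x = X + u(X)`: a finite-element model of the LV
wall, built on the template, is deformed by image-based body forces

    f = psi (T(X) - S(phi)) dS/dphi

(mismatch sets the magnitude, the target's intensity gradient the
direction) while its transversely isotropic hyperelastic strain energy
regularizes the map. Because image intensity alone cannot supply the
global systolic contraction, a subject-specific **active contraction**
adds a time-varying-elastance fiber tension

    T_a = Tmax Ca0^2 / (Ca0^2 + ECa50(l)^2) * psi_a * Ct,
    ECa50(l) = Ca0max / sqrt(exp(B (l - l0)) - 1),  l = lambda * lr,

driven by the mean template-target intensity mismatch `Ct` over the mesh:
the model contracts while it is misaligned and stops as registration
completes. The output is the Green-Lagrange strain `E = (F'F - I)/2`
projected onto local circumferential and radial directions, sampled on
the standard 4-regions x 3-depths layout per short-axis slice, plus the
comparison statistics used to validate such strain maps against tagged
MRI (R^2, %RMSE, Bland-Altman, paired t-test).

The package is aimed at cardiac image-analysis researchers who want a
self-contained, testable implementation of the method: a synthetic LV
phantom with analytic ground-truth strain, the registration engine, the
sensitivity-study degradations (additive Gaussian noise at fixed SNR,
intensity scaling, fiber-angle perturbation, active-contraction
ablation), and the strain comparison statistics.

## Worked example

Register the default synthetic phantom pair and compare recovered strains
with the analytic truth:

```r
library(warpstrain)

spec <- PhantomSpec()              # 64 x 64 x 16 at 3 x 3 x 7 mm
pair <- makePhantomPair(spec)      # template, target, truth table, mesh
fibers <- assignFibers(pair$mesh, c(-82, 0, 80), pair$frames)

res <- register(pair$template, pair$target, pair$mesh, fibers)
cat(sprintf("energy reduction %.3f\n", energyReduction(res)))

strains <- recoveredStrains(pair$mesh, finalDisplacement(res), pair$frames)
pred <- sampleHarpGrid(pair$mesh, strains,
                       slices = unique(pair$truth$slice))
cmp <- compareStrains(pair$truth, pred)
cat(sprintf("R2 circumferential %.4f  radial %.4f\n",
            cmp$circumferential$r_squared, cmp$radial$r_squared))
cat(sprintf("%%RMSE circumferential %.3f  radial %.3f\n",
            cmp$circumferential$percent_rmse, cmp$radial$percent_rmse))
```

Output (a few minutes on one CPU):

```
energy reduction 0.880
R2 circumferential 0.9346  radial 0.8688
%RMSE circumferential 0.203  radial 0.137
```

Reading: the registration removed 88% of the image-mismatch energy; the
recovered circumferential (shortening, negative) and radial (thickening,
positive) strains correlate with the analytic ground truth with R^2 of
0.93 and 0.87 across the region-by-depth sampling grid, with
root-mean-square errors of 20% and 14% of the reference strain per
sample. Re-running with `active_on = FALSE` (the ablation control) leaves
substantially more residual energy and degrades both R^2 values — the
active contraction performs the global alignment that image forces alone
cannot.

A shell interface wraps the same functions:

```sh
warpstrain phantom --out phantom_dir/
warpstrain degrade --in phantom_dir/template.nii.gz --snr 8 --seed 1 --out noisy.nii.gz
warpstrain register --template phantom_dir/template.nii.gz \
                    --target phantom_dir/target.nii.gz --out run_dir/
warpstrain compare phantom_dir/truth.csv run_dir/strains.csv
```

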