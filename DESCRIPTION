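Package: warpstrain
Title: Hyperelastic Warping of Gated Cardiac Image Volumes for Left-Ventricular Strain Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element deformable image registration (hyperelastic
    warping) of gated cardiac image volume pairs, with a transversely
    isotropic passive myocardium model and a subject-specific time-varying
    elastance active-contraction stress driven by the mean template-target
    intensity mismatch. Provides a truncated prolate-spheroid left-ventricle
    hexahedral mesh generator with transmural fiber fields, a PET-like
    synthetic left-ventricle phantom with analytic ground-truth systolic
    strain, image degradation transforms (additive Gaussian noise at fixed
    signal-to-noise ratio, intensity scaling) for sensitivity studies, and
    Green-Lagrange strain extraction with region-by-depth sampling and
    method-comparison statistics (coefficient of determination, percent
    root-mean-square error, Bland-Altman limits of agreement, paired t-test).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
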