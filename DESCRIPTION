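Package: eccshoulder
Title: Isokinetic Dynamometry, 1D Statistical Parametric Mapping and
    Muscle DTI Tractography for Shoulder Training Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis tools for randomized-controlled
    eccentric-training studies of the shoulder rotator cuff: zero-lag
    Butterworth filtering and repetition segmentation of isokinetic
    dynamometer trials, isokinetic-phase extraction and body-mass
    normalized 101-node torque-angle curves, three-parameter exponential
    modelling of passive torque-angle flexibility with maximal and
    submaximal range-of-motion inversion, one-dimensional statistical
    parametric mapping (mixed repeated-measures ANOVA F fields with
    random-field-theory and permutation thresholds), cohort statistics
    (mixed MANOVA with Wilks' lambda, paired t, Cohen's d, partial
    eta-squared, z-score outlier screening), and deterministic
    Runge-Kutta diffusion-tensor tractography of muscle fascicles with
    length, volume and fractional-anisotropy metrics. A synthetic-data
    module generates dynamometer trials, cohorts and pennate-muscle DTI
    phantoms with known ground truth so the full pipeline is testable
    without any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
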