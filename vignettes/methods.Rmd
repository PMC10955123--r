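---
title: "Models and methods behind eccshoulder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eccshoulder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccshoulder)
```

eccshoulder implements the analysis chain of pre/post eccentric-training
studies of the shoulder rotator cuff: dynamometry preprocessing, passive
flexibility modelling, curve-level inference by one-dimensional statistical
parametric mapping (SPM), cohort statistics, and DTI-based fascicle
metrics. This vignette documents the models, their assumptions, the
tunable parameters, and the numerical decisions — in particular those the
package had to settle where measurement conventions are not standardized.

## Dynamometer signal chain

Channels arrive as uniformly sampled series (200 Hz by convention) of time,
joint angle (degrees; 0 at the lever perpendicular to the body, positive
toward external rotation), torque (Nm) and angular velocity (deg/s).

**Zero-lag filtering.** `filter_zero_lag()` applies a 5th-order Butterworth
low-pass (6 Hz cutoff) forward and backward, so the effective magnitude is
the squared Butterworth response and the net phase shift is zero — the
standard treatment for movement signals, where phase lag would bias angle
alignment. Coefficients come from `signal::butter()`; the forward-backward
application itself is done in-package with odd-reflection padding and
steady-state initial conditions, because a zero-initialized IIR pass leaves
a start-up transient that visibly distorts the first half-second of a slow
trial (a constant input should come back unchanged to machine precision,
and does). Filtering requires more than `3*(order+1)` samples; shorter
series are rejected with the minimum stated.

**Segmentation.** Repetitions are maximal runs of constant velocity sign.
Runs shorter than `min_duration = 0.1` s are treated as chatter around the
direction reversals and dropped. Positive velocity (angle increasing) is
labelled `external`, negative `internal`. A trial with no zero-crossing
yields a single segment plus a warning rather than an error, since
single-direction captures occur in practice.

**Isokinetic phase.** Within a repetition, the phase is the longest
contiguous run with `|velocity|` inside `(1 ± tol) * target_speed`. No
standard tolerance exists for this decision; the package default is
`tol = 0.10`, exposed as an argument, and the phase reduces exactly to the
generator's constant-velocity plateau as `tol -> 0`. The acceleration and
deceleration portions are thereby excluded, which matters because torque
during those portions reflects inertia as much as muscle.

**Normalization and resampling.** Torque is divided by body mass (Nm/kg),
and each phase is interpolated linearly in angle onto 101 equally spaced
nodes between its angle extremes (0–100% of the isokinetic ROM). Linear
interpolation is exact on affine segments, shape-preserving, and — with
duplicate angles averaged first — monotone-safe. Endpoints are copied
exactly. 101 nodes is the standard grid for 1D SPM. Per-subject strength
aggregates use the best repetition's peak and the mean of the repetitions'
means; both rules are arguments, since testing conventions differ and the
choice is rarely reported.

Percent change is reported as `100*(post - pre)/pre` rounded to two
decimals, computed from group means of absolute (non-normalized) values as
pre/post tables conventionally print them.

## Passive flexibility model

Passive torque against stretch angle is modelled as the three-parameter
exponential `T(θ) = a·e^{bθ} + c` (a in Nm, b in 1/degree, c in Nm) — the
standard stiffness description for passive joint structures, where `b`
captures the exponential rise of elastic resistance. An alternative
shifted form `a·(e^{b(θ−θ₀)} − 1)` is available behind `form = "shifted"`
for sensitivity analyses; published work using "a three-parametric
e-function" does not always print the exact form, so both are provided and
the offset form is the default.

Fitting is nonlinear least squares with a fully deterministic start:
`b` from a log-linear regression of torque first differences on angle
(since `dT/dθ = ab·e^{bθ}` is log-linear in θ), then `a, c` by a linear
solve at that `b`. Refinement uses Levenberg–Marquardt
(`minpack.lm::nls.lm`) with an analytic Jacobian and parameter tolerance
1e-10. The raw optimizer is used rather than an `nls` wrapper because the
wrapper rejects zero-residual (noise-free) problems with a spurious
singular-gradient error. Non-convergence is flagged on the result, never
silent. Near-linear data make `(a, c)` unidentifiable as `b -> 0`; fits
with `|b|·span < 0.05` carry an `ill_conditioned` flag.

ROM extraction inverts the fit at a torque criterion:
`ROM(T*) = min(ln((T*−c)/a)/b, cap)`. Defaults follow the common protocol:
9 Nm for maximal passive ROM, hard caps 100° (internal) / 140° (external).
The submaximal threshold is not standardized; the package default of
4.5 Nm (half the maximal criterion) is an explicit stand-in, surfaced as an
argument and recorded in results. When the threshold does not exceed the
asymptote `c` the cap is returned with a warning. Active ROM averages the
per-cycle extreme angles in the tested direction, requiring at least two
direction reversals.

## One-dimensional SPM

`anova_field()` computes, at each of the Q = 101 nodes, the 2 (group,
between) × 2 (time, within) mixed-model ANOVA with subject as random
blocking factor, by explicit sums-of-squares decomposition on cell/subject
means (group is tested against the between-subject stratum, time and
interaction against the within-subject residual). The decomposition is
algebraically identical to the GLM route but transparent, vectorizes over
nodes, and is verified at Q = 1 against `stats::aov` to 1e-10 in the test
suite. With two within-subject levels, sphericity holds automatically, so
no correction is required. Effect sums of squares that are negligible
against the data scale (identical curves) are clamped to exact zeros
rather than returned as 0/0 artifacts.

**Smoothness.** Random-field-theory (RFT) inference needs the field
smoothness. With residual curves `r_i(q)` (within-cell residuals),
`v(q) = Σ_i r_i'(q)² / Σ_i r_i(q)²` is the squared gradient of the
variance-normalized residual field (central differences, one-sided at the
ends), and `FWHM = sqrt(4·ln 2 / v̄)` with `v̄` the node average. Constant
nonzero residual rows (zero gradient) are reported as effectively
infinitely smooth with a warning; zero-variance residuals are an error.

**Threshold.** The critical height solves
`P(F > u) + R·ρ₁(u) = α`, with `R = (Q−1)/FWHM` resels and `ρ₁` the 1D
Euler-characteristic density of an F field with the effect's degrees of
freedom; bisection to 1e-6, bracketed from the scalar F quantile (its
`R -> 0` limit). Threshold-level inference (suprathreshold clusters with
extent and max F) is reported, matching how torque-curve SPM figures are
read; cluster-level p values are deliberately out of scope.

**Permutation oracle.** `permutation_threshold()` computes the `(1−α)`
quantile of the max-over-nodes F under permutations that respect
exchangeability per effect: group labels permuted between subjects (group,
interaction), pre/post flipped within subjects (time). All distinct
rearrangements are enumerated exactly when their count does not exceed
`n_perm`. RFT is the primary inference; the permutation route is always
available as the nonparametric cross-check, and the test suite requires
the two thresholds to agree within 10% on smooth nulls.

The test suite calibrates the whole chain: on null synthetic cohorts
(14 + 11 subjects, Q = 101, smoothness matched to an FWHM-15 kernel) the
familywise rejection rate at the RFT threshold must lie within 5% ± 1.5%
over 2000 replicates. These problem sizes mirror the cohort sizes the
package targets while keeping the suite quick.

## Cohort statistics

`mixed_anova_2x2()` shares the SPM sums-of-squares core at Q = 1; its
interaction p value is the between-group "difference in change" test that
pre/post tables print as `Dif`. `manova_mixed()` handles one between factor
(group) and one within factor (time) over a bundle of dependent variables:
with two time points the within-subject information is carried exactly by
the per-subject difference scores, so the time effect tests the grand mean
of the differences, the interaction their group difference, and the group
effect the subject means — each via Wilks' `Λ = det(E)/det(E+H)` with
Rao's F approximation (exact for single-df effects) and multivariate
`ηp² = 1 − Λ^{1/s}`. Sum-to-zero coding makes the intercept the unweighted
grand mean, so tests are marginal (Type-III-like) and robust to unequal
group sizes. Designs with several within factors (e.g. time × mode × speed
bundles) are not decomposed multivariately; bundles of within-cells are the
supported idiom, a documented limitation. A singular error matrix is an
error reporting its condition number.

Paired tests are hypothesis-dependent by policy: one-sided in the
hypothesized improvement direction for pre-registered intervention
contrasts, two-sided otherwise — both configurable. Cohen's d for paired
data is `mean(diff)/sd(diff)`, linked to the t statistic by `d·√n = t`,
an identity the tests exploit to check printed (d, p) pairs for internal
consistency. Outlier screening z-transforms each parameter within group
and excludes `|z| ≥ 2.5` in a single pass; iterating the exclusion would
change the sd and is deliberately not done.

## Muscle DTI

`fit_tensor_lls()` solves `ln(S_i/S0) = −b·gᵢᵀDgᵢ` by ordinary least
squares on the six unique tensor elements; at least six non-collinear
gradients are required and rank deficiency is an error. Negative
eigenvalues (possible under noise) are clamped to zero with a warning.
Fractional anisotropy uses the standard normalized eigenvalue dispersion.

`track_streamline()` integrates the principal-eigenvector field
bidirectionally from a seed with classical RK4 at a fixed step (1 mm
default). Tensors are interpolated component-wise (trilinearly) and
eigen-decomposed at each evaluation point — smoother than interpolating
eigenvectors, whose sign ambiguity would corrupt averaging; the sign is
aligned to the previous direction at every evaluation. Stop rules: leaving
the mask, FA outside `[0.05, 0.6]`, turning more than 30° per step, or
exceeding the 200 mm length cap; accepted fascicles must also reach 10 mm.
These values are all arguments: published muscle-tractography stop
criteria live in protocol-specific prior work, so the defaults here are
explicitly provisional and recorded with the outputs. Seeding is one seed
per masked voxel center in deterministic index order (an evenly spaced
subset when a cap is requested). Fascicle length is the mean streamline
arc length; fascicle volume counts unique voxels traversed times the voxel
volume — the tract-voxel convention of common tractography statistics
tools, flagged here because "fascicle volume" is not otherwise defined;
bundle FA is length-weighted.

The integrator is exposed separately (`integrate_direction_field()`)
because order-of-convergence checks must run on an analytic direction
field: on the voxel grid, trilinear interpolation contributes an
O(voxel²) error that is independent of the step size and would mask the
integrator's O(h⁴). On an analytic circular-arc field the test suite
requires the endpoint error to shrink at least 12-fold per step halving
(the theoretical factor is 16), against 2-fold for the Euler reference.

## The synthetic-data module

The generators define the study conditions the package is tested under;
they are first-class, tested code.

* **Active trials**: a trapezoidal velocity profile per repetition (ramp
  over `accel_time`, plateau at the commanded speed, ramp down;
  repetitions alternate direction) with torque a Gaussian bell in angle
  (configurable optimum, width, peak) plus additive Gaussian noise. The
  bell is a deliberate stand-in: raw torque-curve shapes of real shoulders
  are not standardized, and nothing downstream depends on the exact shape
  — only on smoothness and unimodality. A training effect is injected by
  scaling the peak and shifting the optimum rightward (toward the
  stretched position), the signature eccentric-training adaptation.
* **Passive trials**: angle advances at 10 deg/s; torque follows
  `a·e^{bθ} + c` plus noise; motion reverses at the 9 Nm criterion or the
  angle cap, whichever comes first; ten alternating stretch cycles by
  default. Ground-truth reversal angles are returned.
* **Cohorts**: per-subject random intercepts (between-subject sd) plus
  occasion noise (within-subject sd); intervention post means shifted by a
  configurable percent effect. Defaults (14 vs 11 subjects, 15% effect on
  eccentric peak torque at 30 deg/s, baseline means near 40 Nm with ~8 Nm
  between- and ~3 Nm within-subject sd, body mass 84.8 ± 11.3 kg) mirror
  the junior-athlete cohorts this pipeline targets.
* **DTI phantoms**: a cylindrical muscle mask filled with straight (or
  circular-arc) fascicles of known arc length; each masked voxel carries a
  tensor whose principal eigenvector is tangent to the local path and
  whose transverse eigenvalues are solved in closed form so the FA equals
  the target exactly; optional DWI synthesis over a 48-direction
  Fibonacci gradient table at b = 400 s/mm² with Gaussian or Rician noise.

What the generators do *not* emulate — and hence what green tests do not
establish about real data: dynamometer compliance and inertial ringing,
gravity-correction residuals, EMG-confirmed passivity, viscoelastic
(time-dependent) passive behaviour, partial-volume and susceptibility
effects in DWI, motion/eddy-current artifacts, and anatomically curved
pennate geometry beyond the arc option. Results on real data additionally
depend on segmentation quality and protocol standardization.

All random draws flow from explicit seeds; derived sub-seeds keep the
draw streams of different stages independent, so adding a parameter to one
stage never reorders another's stream. Identical spec + seed reproduces
outputs bitwise.

## Numerical and design decisions

* Index ranges are 1-based inclusive everywhere, the R convention.
* Interpolation grids preserve endpoint values exactly; duplicate angles
  are averaged before interpolation.
* `fit_efunction` tolerances: ftol 1e-14, ptol 1e-10, 500 iterations.
* RFT bisection tolerance 1e-6 on the threshold height.
* The permutation quantile uses the default empirical quantile (type 7)
  of the max distribution, identity permutation included.
* Percent changes recomputed from printed (rounded) group means cannot
  always reproduce a printed percent change; `reproduce_tables()` reports
  a rounding-feasibility flag (means known to half a printed unit) next
  to the exact two-decimal match, and the worked tables bundled in
  `extdata` show both sign-dropped and rounding-casualty rows, which the
  flags identify rather than hide.
* α = 0.05 throughout.

## Known limitations

Only two-level within designs are supported (pre/post); longer time series
would need sphericity handling. MANOVA is limited to one between and one
within factor over DV bundles. No cluster-level RFT p values. No
viscoelastic passive modelling, no probabilistic tractography, no
eddy-current or motion correction (upstream concerns), no device-specific
binary formats — trials are exchanged as plain CSV/TSV, phantoms as NIfTI
with JSON sidecars.
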