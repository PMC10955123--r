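# eccshoulder

Analysis tools for randomized-controlled eccentric-training studies of the
shoulder external rotators, covering the full measurement chain of such
studies: isokinetic dynamometer signal processing, passive flexibility
modelling, one-dimensional statistical parametric mapping (SPM) of
torque-angle curves, cohort statistics, and diffusion-tensor (DTI) muscle
fascicle metrics. A first-class synthetic-data module generates dynamometer
trials, pre/post cohorts and pennate-muscle DTI phantoms with known ground
truth, so every downstream stage is testable without any acquisition or
download.

## Who it is for

Biomechanics and sports-medicine researchers who collect isokinetic
strength / range-of-motion (ROM) data and muscle diffusion MRI in pre/post
intervention designs (e.g. overhead athletes at risk of glenohumeral
internal rotation deficit), and want a reproducible, tested pipeline from
raw 200 Hz dynamometer channels and tensor volumes to publication-style
tables, curve-level inference and fascicle metrics.

## What it computes

**Dynamometer branch.** Raw angle/torque/velocity series are low-pass
filtered with a 5th-order zero-lag Butterworth filter (6 Hz cutoff), cut
into directional repetitions at velocity zero-crossings, reduced to the
isokinetic phase (the longest run with |velocity| within ±10% of the
commanded speed, excluding acceleration/deceleration), normalized to body
mass, and linearly interpolated to 101 nodes over 0–100% ROM. Peak and mean
torque per repetition feed per-subject strength records and percent changes
`100·(post − pre)/pre`.

**Passive flexibility.** Averaged passive stretch trials are fitted with the
three-parameter exponential `T(θ) = a·e^{bθ} + c` (deterministic
initialization, Levenberg–Marquardt refinement). Maximal ROM is the angle
where the fit reaches 9 Nm — capped at the hard angle limit (100° internal /
140° external) — and submaximal ROM the same inversion at a configurable
lower threshold:

    ROM(T*) = min( ln((T* − c)/a)/b , cap )

**1D SPM.** At every node of the 101-node grid a 2 (group) × 2 (time) mixed
repeated-measures ANOVA yields F fields for group, time and interaction.
Familywise inference over the field uses random field theory: the residual
smoothness (FWHM) is estimated from the mean squared gradient of
variance-normalized residuals, and the critical threshold solves
`P(F > u) + resels · ρ₁(u) = α` with `resels = (Q−1)/FWHM` and ρ₁ the 1D
Euler-characteristic density of an F field. A max-statistic permutation
threshold (exact enumeration when feasible) is available as a nonparametric
cross-check.

**Cohort statistics.** Mixed MANOVA with Wilks' Λ (Rao's F, multivariate
ηp² = 1 − Λ^{1/s}), univariate mixed ANOVA with partial
η² = F·df₁/(F·df₁ + df₂), hypothesis-dependent paired t tests, paired
Cohen's d (`d = t/√n`), and single-pass z-score outlier screening (|z| ≥ 2.5).

**Muscle DTI.** Log-linear least-squares tensor estimation from DWI signals
(48 directions, b = 400 s/mm² by default), fractional anisotropy, and
deterministic streamline tractography of the principal-eigenvector field
with a classical 4th-order Runge–Kutta integrator (trilinear tensor
interpolation, FA/turning-angle/length stop rules), summarised as fascicle
length, fascicle volume and mean FA.

## Worked example

```r
library(eccshoulder)

sp <- trial_spec(mode = "eccentric", direction = "external", target_speed = 30,
                 rom_start = -60, rom_end = 90, noise_sd_torque = 0.5, seed = 7)
tr <- simulate_active_trial(sp, peak_torque = 40, optimum_angle = 20,
                            n_reps = 3, body_mass = 84.8)
tr
#> <dyn_trial> eccentric external, 30 deg/s, 6306 samples @ 200 Hz
#>   angle [-60.0, 90.0] deg, torque [3.97, 41.24] Nm

tr$torque_Nm <- filter_zero_lag(tr$torque_Nm, 200)
segs   <- Filter(function(s) s$direction == "external", segment_repetitions(tr))
phases <- lapply(segs, extract_isokinetic_phase)
round(subject_strength(phases, body_mass = 84.8), 3)
#>    peak_Nm    mean_Nm peak_Nm_kg mean_Nm_kg
#>     40.246     25.783      0.475      0.304
```

The best-repetition peak (40.25 Nm) recovers the generator's 40 Nm bell peak
through the full filter → segment → isokinetic-phase chain; dividing by the
84.8 kg body mass gives the normalized 0.475 Nm/kg used for curve analysis.

```r
ang <- seq(0, 90, length.out = 300)
f <- fit_efunction(ang, 0.5 * exp(0.05 * ang) + rnorm(300, 0, 0.1),
                   angle_cap = 140)
f
#> <passive_fit> T(theta) = a*exp(b*theta) + c
#>        a        b        c
#> 0.501636 0.049953 0.004736
#>   rmse 0.0988 Nm | converged: TRUE
#>   ROM @ 9 Nm: 57.79 deg | ROM @ 4.5 Nm: 43.90 deg
```

The fitted stiffness parameters sit on the generating values (a = 0.5,
b = 0.05, c = 0) and the 9 Nm inversion reproduces the analytic
ln(18)/0.05 = 57.81° within the noise-induced uncertainty.

```r
res <- run_pipeline(default_config(), "pipeline_out")
res$report
#>     parameter        group           pre          post delta_pct     p      d dif_p
#> 1 ecc_peak_30 intervention  40.85 ± 9.20 46.92 ± 10.60     14.86 0.000  4.306     0
#> 2 ecc_peak_30      control 42.14 ± 11.94 42.13 ± 11.91     -0.02 0.836 -0.064     0
res$spm
#> <spm_anova> group_by_time design, Q = 101 nodes, alpha = 0.05, FWHM = 17.41 nodes
#>   group        F(1,23) max 9.408 | F* = 10.633 | 0 cluster(s)
#>   time         F(1,23) max 219.883 | F* = 10.633 | 2 cluster(s) [1-46] [54-101]
#>   interaction  F(1,23) max 161.631 | F* = 10.633 | 2 cluster(s) [1-45] [55-101]
```

The end-to-end pipeline injects a 15% eccentric peak-torque effect (plus a
rightward optimum-angle shift) into the intervention arm only; the report
recovers 14.86% with a near-zero interaction p, while the control arm stays
flat, and the SPM interaction field localizes the curve-level change.

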