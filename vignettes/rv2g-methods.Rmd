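---
title: "Methods: two-zero-load-geometry ventricle mechanics in rv2g"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-zero-load-geometry ventricle mechanics in rv2g}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rv2g)
```

# The model

## Why two reference geometries

Stress and strain in a beating ventricle are defined relative to a
zero-stress configuration, and that configuration is not constant: active
contraction shortens the zero-stress sarcomere length at the start of
systole and relaxation restores it at the start of diastole. A
one-geometry (1G) model, which carries a single zero-load reference through
the whole cycle, therefore cannot produce end-diastole and end-systole
stress states that differ from begin-systole and begin-diastole. The 2G
scheme approximates the sarcomere-length switch to first order by giving
each phase its own zero-load geometry:

* **Filling (diastole)**: the diastole zero-load chamber is inflated from
  the minimum pressure `Pmin` (begin-filling, BF) to the end-diastolic
  pressure `Pdia` (end-filling, EF).
* **Ejection (systole)**: the model switches instantaneously to the smaller
  systole zero-load chamber at the maximum pressure `Pmax` (begin-ejection,
  BE) and unloads to the end-systolic pressure `Psys` (end-ejection, EE).

The two isovolumic phases (EF to BE and EE to BF) involve a dynamically
changing zero-stress sarcomere length and are omitted; volume is continuous
across the switches (both references are calibrated to the same imaged
volume trace) while stress and strain jump discontinuously. These jumps are
a deliberate feature, not an artifact: they carry the work of active
contraction and relaxation.

Zero-load is used as a computable surrogate for zero-stress; residual
stresses in the unloaded wall are ignored throughout.

## Constitutive laws

The wall is hyperelastic, incompressible and homogeneous. Two families are
implemented:

* the modified Mooney–Rivlin law, isotropic part
  `W = c1 (I1 - 3) + c2 (I2 - 3) + D1 [exp(D2 (I1 - 3)) - 1]`, plus a
  transversely isotropic fiber term `(K1 / 2 K2) [exp(K2 (I4 - 1)^2) - 1]`
  with `I4` the squared fiber stretch;
* the Fung-type exponential `W = (C/2)(exp(Q) - 1)` with `Q` quadratic in
  the fiber-coordinate Green–Lagrange strains, weighted `b1` (fiber–fiber),
  `b2` (cross-fiber/radial block) and `b3` (fiber shear block).

Two notational points deserve care. First, the exponential grouping: the
Mooney–Rivlin exponent is sometimes typeset as `exp(D2 (I1 - 3) - 1)`.
Read literally, that grouping gives non-zero energy and stress in the
reference configuration, contradicting the zero-load construction, so the
package defaults to `exp(D2 (I1 - 3)) - 1` (and the analogous grouping for
the fiber term); the literal variant is available behind the
`literal_grouping` flag of `iso_mr_params()` for comparison. Second,
incompressibility is enforced exactly with a Lagrange pressure fixed by a
traction-free direction, rather than through a nearly-incompressible
penalty; the difference is negligible at physiological bulk-to-shear ratios
and the exact form makes the stress a closed-form function of the
deformation, which the test suite exploits (Cauchy stress is verified
against central finite differences of the energy on random incompressible
states to 1e-5 relative).

`fit_aniso_to_fung()` fits the Mooney–Rivlin parameters to stress–stretch
curves generated from a Fung law by bounded least squares (`optim`
L-BFGS-B) from three fixed starting points; the reported residual is the
RMS stress misfit in kPa.

## From contour stacks to chambers

The geometric substrate is the contour stack: per-slice endocardial and
epicardial closed contours plus a slice spacing, in cm, ordered base to
apex, stored counter-clockwise. All nodal quantities use a common
100-point equal-arc-length resampling whose start point is the contour's
+x-axis crossing from its centroid; that convention index-aligns points
across slices and defines the meridians used for longitudinal curvature
(the source imaging protocol needs no such rule because it keeps mesh
correspondence; a contour-level toolkit must pick one).

* Volumes use disk summation (the cardiology "Simpson" rule): slice area
  times spacing, areas by the shoelace formula.
* Wall thickness at an inner point is the distance to the outer contour
  along the inner outward normal (nearest ray intersection, with a flagged
  nearest-vertex fallback).
* Circumferential and longitudinal curvatures are unsigned, estimated by
  least-squares circle fits over sliding windows (7 points of 100 in-slice;
  5 slices along meridians). The estimator and signedness are package
  choices — the quantities are reported in the literature without either
  being specified — and window sizes are configurable arguments.

The forward model reduces a stack to a **volume-equivalent thick-walled
sphere**: zero-load inner radius from the cavity volume, outer radius from
cavity plus wall volume. This is the package's largest deliberate
departure from the source methodology, which solved 3D anisotropic
finite-element models on patient-specific hexahedral meshes. The reduction
is adopted because every quantity the downstream analysis consumes —
pressure–volume behavior, transmural mean maximum-principal stress and
strain at the four landmarks, their phase discontinuities — survives it,
while the kinematics become closed-form (`r^3 = R^3 + ri^3 - Ri^3`) and
admit exact oracles: the luminal pressure is
`p = \int 2(sigma_theta - sigma_r)/r dr` with
`sigma_theta - sigma_r = (lambda/2) w'(lambda)` from the reduced
equibiaxial energy. The radial-stress boundary conditions (`-p` at the
inner wall, `0` at the outer wall) are verified on every inflation. Under
spherical symmetry the equibiaxial wall state makes the fiber stretch
independent of the in-plane fiber angle, so the two-layer fiber-angle
assignment affects fiber-frame strain reporting only — a documented
limitation of the reduction. Regional quantities (patch/scar inclusions,
local stress maps) are out of scope.

Deformed-configuration geometry metrics (`extract_phase_metrics()`) map a
landmark volume back to the source stack by scaling the inner contours and
slice positions isotropically and setting each outer contour by wall-volume
conservation, so wall thickness thins and circumferential curvature drops
as the chamber inflates, as an incompressible wall requires.

## Zero-load recovery (pre-shrink)

In vivo the ventricle is never unloaded, so the zero-load geometry is
recovered inversely: shrink the imaged minimum-volume geometry slice by
slice (inner contour by rate `r`, outer contour by the smaller factor that
conserves the wall cross-sectional area of the slice, slice spacing by a
coupled axial rate), pressurize the result, and adjust `r` until the
pressurized volume matches the imaged volume to 0.5%. The update rule is a
secant iteration with a bisection fallback, justified by the strict
monotonicity of inflated volume in the shrink rate (asserted numerically in
the test suite). Phase conventions: diastole starts from 2% shrinkage and
uses the begin-filling pressure; systole starts from 15% (an assumed 10–15%
sarcomere shortening) and uses the end-systole pressure. The axial rate is
coupled 1:1 to the in-plane rate by default — the long-axis reduction is
known to occur but its magnitude is not specified anywhere, so the package
exposes it (`axial_ratio`) rather than asserting a value. Shrinkage centers
are per-slice inner-contour centroids, and conservation is per-slice rather
than whole-wall, matching the slice-wise description of the procedure.

A full patient calibration (`calibrate_phase()`, `build_2g_model()`) must
satisfy two imaged volumes per phase — the minimum at the low-pressure
landmark and the maximum at the high-pressure landmark — with two scalar
unknowns: the shrink rate and a single multiplicative stiffness factor on
the stress-like material parameters (`scale_stiffness_to_volume()`). The
two one-dimensional solves are alternated to convergence. Feasibility
depends on the material's strain-stiffening: a law that stiffens too
quickly cannot span a 1.6x volume swing across the systolic pressure range
with any scale factor, because rescaling stiffness only slides the
pressure–volume curve along the pressure axis. The shipped defaults
(`default_material()`: diastole c1 = 1 kPa, D1 = 0.25 kPa, D2 = 1, K1 = 2
kPa, K2 = 1; systole the same shape scaled 8x stiffer; isotropic patch and
scar sets) were chosen once to be physiologically compliant in this sense
— a gentle exponential toe region that supports imaged ejection fractions
near 40% under RV pressures of 0.3–8.7 kPa — since the source publishes
stress–stretch curves only graphically, without parameter values. The
default pressure schedule (Pmin 0.3, Pdia 1.3, Pmax 8.7, Psys 2.7 kPa) is
likewise a configuration placeholder on the RV scale, not measured data,
and every analysis accepts patient-specific values.

# Cohort analysis

## Statistics

Group comparisons use the equal-variance Student t-test (the unpaired
comparison named by the source; Welch available behind a flag), pairwise
model comparisons the paired t-test, and slice-clustered comparisons a
random-intercept-per-patient linear mixed model fitted by REML (profiled
restricted likelihood over the variance ratio, via lme4) with a Wald p for
the condition effect — only that fixed-effect p is surfaced. Singular fits
(between-patient variance on the zero boundary) are returned flagged, where
the model degenerates to the pooled comparison. Associations with the
outcome (change in RV ejection fraction, ΔEF, pre- to 6 months post-PVR)
use Pearson correlation with the t transform on n − 2 degrees of freedom.
Normality (checked in the source for the n = 16 analyses) is reported via
Shapiro–Wilk p-values in `group_summary()` output but never gates an
analysis.

## Outcome prediction

Eight candidate predictors are assembled per patient: wall thickness,
circumferential and longitudinal curvature, end-diastolic volume, the
begin-ejection stress, and its differences to the end-filling, end-ejection
and begin-filling stresses (StressE-D, StressE-F, StressE-C). All 255
non-empty subsets are scored by logistic regression under 20 repeats of
2-fold cross-validation, with the AUC average and a 2.5/97.5-percentile
confidence interval taken over 100 rounds.

Several protocol details are underdetermined in the source and were fixed
as follows, each with a switch where reasonable:

* **Stratified folds** (4 + 4 per group per fold). Unstratified random
  halves of 16 patients frequently produce single-class folds, for which
  neither a fit nor an AUC is defined; stratification removes the failure
  mode (`stratified = FALSE` restores plain random splits with re-draws).
* **Pooled-per-repeat AUC**: the two held-out half-cohort score vectors of
  a repeat are pooled into one AUC (8 + 8 scores). The per-fold variant
  (AUC per half, averaged) is available via `pooling = "per-fold"`; pooling
  has the lower variance at this n. The printed source table carries both a
  single "AUC" and an "AUC Average" column, consistent with two estimators
  being in play.
* **Ridge penalty 1e-3** on z-scored predictors (intercept unpenalized).
  Several subsets separate 16 points perfectly; unpenalized maximum
  likelihood then diverges. The penalty is small enough to leave
  non-separable fits indistinguishable from `glm` (verified to 1e-6 at zero
  penalty in the tests) while keeping every fold fittable.
* **Cutoffs** maximize sensitivity + specificity (Youden), ties broken
  toward higher specificity. The published per-subset probability cutoffs
  are not reproduced: their averaging scheme across runs is unstated.
* **Determinism**: round `r` seeds the RNG with `base_seed + r`, and the
  ranking engine reuses identical fold splits across all 255 subsets, so
  subset comparisons are paired and the whole pipeline is reproducible from
  one integer.

The cohort itself ships as fixtures: the published per-patient tables
(demographics and volumes; 1G/2G phase stresses; phase strains;
begin-ejection metrics with outcome group) transcribed verbatim to CSV with
checksums. Transcription is itself tested: every printed summary row is
recomputed from its per-patient rows, to within three-quarters of the last
printed digit. Three printed cells fail any such check and are shipped
as printed, flagged rather than corrected: the group-2 EDV mean (387.4
printed, 387.69 recomputed), the group-1 EDV SD (93.7 vs 93.93), and the
demographics table's pooled summary row, which mixes group-2-only values
(its ΔEF of −11.1 ± 4.4 is the group-2 row) and is excluded from the check.
The printed correlation row is reproducible only to about 0.01–0.02 — it
was evidently computed from unrounded source data — and is tested at that
tolerance. Where the running text and the tables disagree (begin-ejection
group stresses 130.1/82.7 in the text vs 133.9/82.9 in the tables), the
fixtures follow the tables.

# Synthetic data

Two generators make every pipeline stage testable without any imaging
data; both are deterministic given their spec's seed.

* `generate_ventricle()`: a truncated half-ellipsoid (base plane to 90% of
  the long axis), inner surface the ellipsoid cross-sections, outer surface
  the wall-offset ellipsoid, optional multiplicative Gaussian radial noise.
  Defaults (semi-axes 4, 4, 8 cm, wall 0.45 cm, 13 slices, 100
  points/slice) give cavity volumes near 260 cm^3 — the scale of the
  dilated RVs in the shipped cohort (EDV 188–665 cm^3) — with the 12–14
  slice coverage of the imaging protocol. What it does not emulate:
  crescent-shaped RV cross-sections, the outflow tract, patch/scar regions,
  trabeculation, and segmentation error structure beyond white radial
  noise. Passing tests on these stacks validate the geometric and inverse
  machinery, not anatomical fidelity.
* `generate_cohort()`: two outcome groups with Gaussian begin-ejection
  stress (defaults: the printed group means/SDs, 82.9 ± 27.5 vs 133.9 ±
  31.4 kPa, ratio 1.615), ΔEF constructed as a linear decreasing function
  of stress plus Gaussian noise calibrated so the population correlation is
  −0.6 and the ΔEF SD 7.6% (slope −ρ·σ_ΔEF/σ_stress against the pooled
  stress SD including the between-group component), other phase stresses
  tied to the begin-ejection value by the cohort-mean ratios (EF 0.398, EE
  0.266, BF 0.066) with 10% lognormal jitter, and group-independent
  geometry columns on the printed cohort's scale. The linear ΔEF model is
  purely a test instrument — it makes planted effects recoverable, it is
  not a physiological claim. A null configuration (ratio 1, correlation 0)
  exists for calibration tests, where group-test p-values are checked to be
  uniform across seeds.

# Numerical choices and problem sizes

* Inflation root-finding: `uniroot` on the deformed inner radius to
  `1e-10 * Ri`; pressure integral by adaptive quadrature at 1e-8 relative
  tolerance (refinement to 1e-11 moves volumes by < 1e-6 relative, tested).
  Pressures beyond the material's supportable range raise a distinct error.
* Pre-shrink: volume tolerance 0.5% relative, iteration cap 50, negative
  iterates clamped at 0; the recovered rate reproduces a planted rate to
  1e-3 on noise-free stacks.
* Stiffness calibration: bracketed root search on log10(factor) in
  [−3, 3]; an unreachable target raises a calibration-failure error rather
  than returning a boundary value.
* Degenerate inputs: zero-perimeter contours, non-monotone slice
  positions, zero wall volume, single-class labels, zero-variance vectors
  and constant score vectors all raise typed errors or take documented
  shortcuts (exact-equality t-test conventions, curvature 0 for collinear
  windows).
* Test-suite problem sizes, chosen so the full suite runs on one CPU in
  well under half an hour: 13-slice/100-point stacks, 25-slice spheres for
  curvature benchmarks, 500 null simulations for the mixed-model type-I
  calibration (8 patients x 6 slices), 50 generator seeds at 2 CV rounds
  for the planted-effect ranking property, and the full 255-subset ranking
  at the complete 100-round protocol.

# Known limitations

* The equivalent spherical chamber has no regional variation: no
  patch/scar inclusions, no crescent RV geometry, no septal interaction
  with the LV, and fiber angles do not influence the mechanics (only
  fiber-frame reporting). Conclusions about regional stress cannot be drawn
  from it.
* Quasi-static: inertia is dropped from the momentum balance, so the
  solution is periodic by construction and rate effects (and the source's
  three-cycle settling) have no counterpart.
* Zero-load stands in for zero-stress; residual wall stresses are ignored.
* The mixed-model p-value is a Wald normal approximation; at very small
  cluster counts it is slightly anti-conservative (the type-I calibration
  test brackets it at 3–7% for the sizes used here).
* With n = 16 patients, cross-validated AUCs carry substantial variance;
  the 100-round averaging stabilizes the estimate but cannot substitute for
  a larger cohort, and the ranking among closely spaced subsets (the top
  ten AUC averages differ by ~0.01) is not individually meaningful.
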