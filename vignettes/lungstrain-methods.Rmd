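---
title: "Respiratory strain analysis from 4D-CT: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory strain analysis from 4D-CT: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungstrain)
```

# The measurement problem

Spirometry summarizes airflow limitation in one global number; it says
nothing about where in the lung motion is impaired. Respiration-resolved CT
(4D-CT), acquired routinely for radiotherapy motion management, images the
lung at ~10 phases of the breathing cycle and therefore carries regional
biomechanical information at no extra cost to the patient. This package
implements a complete analysis chain that turns an end-inspiration /
end-expiration (EI/EE) CT pair into three per-patient biomarkers:

* **PSmax** — the maximum of the first principal strain over the lung,
* **PSmean** — its mean,
* **Speedmax** — the maximum displacement magnitude divided by the
  inter-phase interval (mm/s),

together with end-inspiration densitometry (LAA%, MLD, Perc15) and the
group-level diagnostic statistics used to evaluate such biomarkers in a
two-group (normal lung function vs. COPD) setting.

# Pipeline model and assumptions

## Segmentation

Lung masks come from a four-step threshold-and-morphology workflow:
threshold at **−400 HU** (air-like attenuation), 26-connectivity component
filtering (components < **1000 voxels** and components touching the grid
boundary removed — this discards both noise and the exterior-air
component), morphological closing with a Euclidean **ball of radius 5
voxels** (closing vascular shadows), and n-dimensional hole filling with a
6-connected background. The 26/6 foreground/background connectivity pairing
avoids the usual topological paradoxes; the ball is a true sphere computed
through the exact Euclidean distance transform. Small tumours are
deliberately *not* excluded from the mask: at ≤ 3 cm they occupy < 5 % of
the lung and the pipeline aims at global mechanics (an optional lesion mask
can subtract them).

## Registration

Respiratory phases are aligned by translation only: a centroid-difference
initialization from the two lung masks, refined by maximizing a 32-bin
joint-histogram mutual information (HU clamped to [−1024, 200], metric
restricted to the dilated reference mask). EE is the reference phase (least
motion artifact). The derivative-free search is a Nelder–Mead simplex
followed by two deterministic per-axis line sweeps (±2 mm in 0.25 mm
steps); the sweeps matter because the subsampled MI surface is locally
bumpy and a simplex alone can stall a millimetre from the optimum. The
refinement never returns a shift scoring below its initialization. No
affine or deformable stage is fitted — the deformable part of the motion is
deliberately left to the optical flow.

Registration quality is gated by target registration error (TRE) at paired
landmarks: the case passes only if the maximum landmark error after
translation *and* flow is **< 2 mm**; failing cases are flagged excluded
rather than silently analysed.

## Dense optical flow

Displacement fields are computed slice-wise on axial planes with the
Farneback polynomial-expansion algorithm, written natively in this package:
each image is locally approximated by a quadratic polynomial over a
Gaussian applicability (neighbourhood half-width 5, σ = 1.2), and the
displacement update solves the locally averaged normal equations (box
averaging, window 15) iteratively (3 iterations) over an image pyramid
(scale 0.5, 3 levels). The initial estimate is formed on two-fold
downsampled slices and refined at full resolution. The convention is
`from(x) ≈ to(x + u(x))`, with `u` converted to millimetres via the
in-plane spacing.

Flow is 2-D by construction: the seven canonical parameters define a 2-D
interface, and no through-plane procedure is part of the analysis.
Through-plane motion therefore appears as matching noise, not as measured
displacement — a known and accepted limitation, which is why the axial
component of respiratory motion must be small relative to the slice
thickness after rigid alignment.

## Strain

The infinitesimal strain tensor is the symmetric displacement-gradient,
$\varepsilon_{ij} = \tfrac12(\partial u_i/\partial x_j +
\partial u_j/\partial x_i)$, computed per slice by central differences in
physical (mm) coordinates (one-sided at borders; exact on affine fields).
Principal strains are the closed-form eigenvalues of the symmetric 2×2
tensor, ordered λ₁ ≥ λ₂ and rotation-invariant.

Because differentiation amplifies voxel-scale flow noise, the displacement
field is regularized by a separable Gaussian (default σ = (1, 2, 2) voxels
in (z, y, x)) before the tensor is formed. At this scale, strain structure
with wavelengths of tens of voxels is attenuated by only a few percent
while single-voxel noise is strongly suppressed; σ = 0 disables it.

**Units.** ε is dimensionless, yet clinical reports often quote principal
strain "in millimetres". The summary therefore has two modes: the
dimensionless eigenvalue statistics are always reported, and in the default
`paper_mm` mode they are additionally scaled by the mean in-plane voxel
spacing to produce mm-denominated values comparable with such reports. No
claim is made that the mm numbers are physical lengths.

**Speed.** The rigid translation found by registration carries no strain
but is real motion; it is added back to the flow before the speed
statistic, so `Speedmax = max |u_rigid + u_flow| / dt`. The inter-phase
interval defaults to `dt = 2 s` (half a nominal 4 s cycle) and is
configurable; all quantitative speed checks run on synthetic data where the
generator fixes `dt`.

## Densitometry

Over the EI lung mask: LAA% (fraction of voxels ≤ −950 HU), mean lung
density, and the 15th percentile of the attenuation histogram (Perc15).
The "pixel index PI-15" naming in parts of the literature is defined as a
percentage but reported in HU; only the percentile reading is dimensionally
consistent, so Perc15 is the labeled output while the percentage-below-
threshold variant remains available. Percentiles interpolate linearly
between closest order statistics (R type 7) — at n in the tens the
interpolation rule visibly matters, hence it is fixed and documented.

# The statistics stack

* **Group comparisons** route by Shapiro–Wilk normality (α = 0.05): pooled
  two-sample *t* when both groups pass, Mann–Whitney U otherwise; 2×2
  tables use Fisher's exact test when any expected cell is < 5 and the
  Yates-corrected chi-square otherwise. Effect sizes are pooled-SD Cohen's
  d.
* **Correlation** is Spearman's ρ with mid-ranks and the t-approximation
  p-value.
* **ROC** uses the Mann–Whitney AUC (ties at half credit, identical to the
  trapezoidal rule), DeLong structural-components variance for the 95 % CI
  and the test against 0.5, and a Youden-index cutoff over observed score
  values with a fixed tie-break (highest sensitivity, then the lower
  cutoff). Marker direction is auto-detected from group means and recorded;
  for Speedmax, *lower* values indicate COPD.
* **Correlated AUC comparison** is DeLong's paired test; a degenerate
  variance raises an error instead of returning NaN.
* **Logistic models** are maximum-likelihood fits (IRLS, tolerance 1e−8)
  with Wald odds ratios, `OR = exp(β)` and `CI = exp(β ± 1.96·SE)` exactly;
  complete separation raises an error.
* **Internal validation** is Harrell's bootstrap optimism: refit on each
  resample, score apparent-minus-test performance, subtract the mean
  optimism from the apparent estimate; sensitivity/specificity carry each
  replicate's Youden cutoff to the original sample. Intervals are BCa with
  jackknife acceleration. Replicates missing a class are redrawn and
  counted. Everything is reproducible from one seed.
* **Matching** is greedy 1:1 nearest-neighbour on a logistic propensity for
  the matching covariate (lesion size), caliper ±0.3 cm, cases processed in
  descending propensity, deterministic tie-breaks, no replacement.
* **Power** is the exact noncentral-t two-sample power. At d = 1.114 and
  n = 34/12 this evaluates to ≈ 0.90; published post-hoc figures computed
  with other software can differ by a point or two, and this package
  reports its own computed value rather than matching any printed one.
* **Missing data**: complete-case per analysis, throughout.

# Synthetic data

## The deformable phantom

`makePhantom()` builds an *analytic continuous scene* — two ellipsoidal
lungs of band-limited cosine-sum texture (−850 ± 40 HU, correlation length
1.5 voxels, tanh-compressed so no parenchyma voxel reaches −950 HU),
threaded with ~150 vessel spheres per lung (~2 % volume fraction; real
parenchymal CT contrast is vessel-dominated, and the optical flow needs
those features), inside a +30 HU body cylinder surrounded by air. EI
samples the scene at voxel centres; EE samples it at the numerically
inverted deformation (fixed-point inversion of `x + u(x)`), so both phases
carry *identical* sampling characteristics and the forward displacement
truth is exact at EI voxel centres. An earlier design that resampled a
discrete EI grid gave EE a spatially varying interpolation blur that EI
lacked — a generator artifact producing flow-error stripes — and was
abandoned for the analytic formulation.

The deformation family is a bulk translation (default (2, 1, 2) mm), an
axial compression growing linearly toward the caudal pole (default 4 mm at
the pole: the phantom is a ~0.22-scale thorax, and scaling real
diaphragmatic excursion by the geometric factor gives 2–3 mm), an in-plane
sinusoid (amplitudes (3, 4) mm, wavelength 120 mm — peak in-plane strain
≈ 0.21, placed at the lung interiors), and a small uniform shear (0.02).
Invertibility is guaranteed by a positive analytic Jacobian, checked at
generation. Emphysema is planted as an exact count of voxels in
[−1000, −962] HU (7.3 % of the mask by default), mirrored into EE at the
deformed positions; independent per-scan Gaussian noise (SD 5 HU, clipped
at 2 SD) is added last, with margins arranged so the planted voxels are
exactly the voxels ≤ −950 HU.

What the phantom does **not** emulate: CT reconstruction physics, 4D
binning artifacts, airway trees, lobar fissures, gantry tilt, cardiac
motion, or genuinely 3-D strain. Passing tests on phantoms therefore
validate the computational chain, not clinical accuracy on real scans.

## Why the PSmax field-maximum is not recoverable

PSmax as defined is the *maximum* of λ₁ over ~10⁵ voxels of a
differentiated optical-flow field. The flow's error is not uniform: weak-
texture windows, through-plane motion and window-scale matching ambiguity
produce coherent error blobs whose local gradients exceed the smooth
analytic field's true maximum several-fold, under every configuration we
tried (field regularization, robust percentiles, vessel-rich texture,
noise-free and in-plane-only phantoms). The mean-based statistic (PSmean)
and the displacement-based statistic (Speedmax) recover truth to within a
few percent; the field maximum does not, and the package reports it as
computed rather than tuning toward the analytic value. Consistently,
cohort-level PSmax behaves as a noise-dominated maximum (PSmax/PSmean
ratios an order of magnitude above what any smooth field would give), which
is also the pattern seen in clinical reports of this biomarker — and a
plausible reason PSmax discriminates poorly compared with Speedmax.

## The cohort simulator

`simulateCohort()` draws per-group records whose marginals are truncated
normals *moment-matched* to the published two-group summaries (so bounded
variables — pack-years ≥ 0, lesion size ≤ 3 cm, the GOLD split of FEV₁/FVC
at 70 % — still reproduce the printed means and SDs), joined by a Gaussian
copula. COPD labels are consistent with the drawn FEV₁/FVC by construction.

The headline rank correlations of Speedmax with FEV₁/FVC, FEV₁, MEF₅₀ and
FVC (0.533, 0.445, 0.525, 0.351) are *pooled* quantities over both groups.
Using them directly as within-group copula parameters would overshoot the
pooled value, because the group mean shifts already contribute concordance.
The generator therefore calibrates the within-group latent correlation by
deterministic common-random-number bisection until the pooled Spearman at
the requested group mix matches the target; zero (or even strongly
negative) pooled targets are reachable through negative within-group
correlation. Remaining within-group structure (spirometry
inter-correlations, anthropometrics, densitometry) is fixed at plausible
physiologic values, identical in both groups, and repaired to the nearest
positive-definite matrix when necessary. Binary traits are independent
Bernoulli draws at the per-group rates; mMRC grades respect the dyspnea
(≥ 2) rate.

# Numerical choices and degenerate inputs

* Resampling scales grid shape by the factor and spacing by its inverse,
  with centre-aligned voxel grids; an axis that would fall below 2 voxels
  is an error, as are factors outside (0, 4].
* Ties in extreme-phase selection go to the earlier phase fraction, with a
  warning.
* Textureless volumes make mutual information degenerate: the
  initialization is returned with a warning flag, never a spurious optimum.
* Eigenvalues use the closed form `mean ± sqrt(((eyy−exx)/2)² + eyx²)`;
  symmetry is structural (one off-diagonal slot), not asserted.
* The flow normalization maps [−1024, 200] HU linearly to [0, 255] with
  round-half-to-even (−412 HU → 128); the constants depend only on the
  window so both phase members scale identically.
* Bootstrap replicates with a single outcome class are redrawn and counted;
  BCa intervals fall back to the bootstrap range when the distribution is
  degenerate.
* All simulation entry points (phantom, cohort, bootstrap) take explicit
  seeds and are bit-reproducible.

# Problem sizes used in the shipped checks

The shipped test-and-acceptance material runs entirely on synthetic data at
deliberately modest sizes, chosen to exercise every code path at full
fidelity: the default 64×128×128 phantom (the analysis-resolution scale;
`resampleFactor = 1` because the phantom is generated at the scale the 0.5
preprocessing resample would produce from a clinical scan) across several
seeds for the end-to-end chain; a 32×72×96 phantom for unit-level checks;
null-calibration suites of 1000 replicates at the study's 34/12 group
sizes; cohorts of 2000 per group for simulator-fidelity checks and up to
50 000 per group for moment round-trips.

# Known limitations

* Flow is 2-D slice-wise; through-plane motion is unmeasured and acts as
  noise. Registration is translation-only by design.
* PSmax (field maximum) is noise-dominated; see above.
* The mm scaling of principal strain is a reporting convention, not a
  physical length.
* DICOM support covers uncompressed little-endian axial series with
  identity orientation; oblique and compressed data are rejected.
* The cohort simulator matches first and second moments and targeted rank
  correlations; it does not model heavier tails, missingness mechanisms, or
  site effects.
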