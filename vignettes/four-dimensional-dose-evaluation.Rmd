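---
title: "Four-dimensional dose evaluation of tracking versus fixed-geometry lung SBRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-dimensional dose evaluation of tracking versus fixed-geometry lung SBRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dose4d)
```

## The problem

A free-breathing lung tumour moves by up to ~2 cm per breathing cycle,
mostly craniocaudally. A plan optimized on one static CT therefore does not
describe the dose the patient actually receives. Four-dimensional (4D) dose
evaluation addresses this: the breathing cycle is discretized into N equally
time-binned phases (N = 10 here), a dose distribution is obtained on each
phase geometry, each per-phase dose is warped to a common reference phase
(end-exhale) through displacement vector fields (DVFs), and the warped doses
are averaged with the phase time weights (equal weights 1/N):

$$D_{4D}(p) \;=\; \frac{1}{N}\sum_{k=0}^{N-1} D_k\!\left(p + u_k(p)\right),$$

where $u_k$ maps a reference-phase point to its phase-$k$ position
(pull-back convention; fields supplied in the opposite convention must be
inverted first). `dose4d` implements this accumulation together with the
metrics and statistics needed to compare two delivery philosophies:

* **tracking** (robotic, CyberKnife-like): the beam follows the tumour, so a
  small uniform 5 mm GTV-to-PTV margin suffices;
* **fixed geometry** (gantry/VMAT-like): the plan is created at the
  **mid-ventilation** (MidV) phase — the phase whose craniocaudal tumour
  position is closest to the time average, which removes the systematic
  respiratory error — with a per-patient **van Herk margin**, and the static
  dose cloud stays in room coordinates while the anatomy moves through it.

## Data model and conventions

All rasters (`scalar_volume`, `binary_mask`, `displacement_field`) share a
`grid_geometry`: shape, spacing (mm) and the world coordinate of the first
voxel centre. Axes are x = left-right, y = anterior-posterior, z =
superior-inferior; the SI axis must be identifiable because MidV selection
operates on craniocaudal positions. Mask membership is a whole-voxel,
centre-in-region test — there is no partial-volume weighting, so very small
structures (the cohort minimum is a 0.6 cc GTV, ~5 voxels across) carry a
one-voxel-shell uncertainty in any volume or DVH quantity. Dose sampled
outside a grid's extent is 0: dose outside the calculated region is unknown
and zero is the conservative choice.

Margin expansion (`expand_mask`) uses the ellipsoidal per-axis-scaled
distance $\sum_i (\Delta x_i/m_i)^2 \le 1$, so anisotropic van Herk margins
apply directly and uniform margins reduce to Euclidean dilation.

## The synthetic 4D phantom

No public 4D CT accompanies this kind of study, so the package generates its
own ground truth. A phantom is an ellipsoidal body (half-axes 100, 80,
100 mm), two ellipsoidal lungs (42, 60, 85 mm at x = ±50), a spherical GTV
inside one lung, cylindrical cord/esophagus/trachea and a spherical heart,
rasterized at 2.5 mm isotropic spacing on an 80 × 64 × 80 grid. These sizes
were chosen once so that the largest cohort tumour (77.9 cc) with the
largest motion (22.8 mm) and its PTV margins stays inside the lung at every
phase; the grid spacing matches a typical clinical dose grid.

**Breathing.** Centroid offsets follow the classic $\cos^{2n}$ model,
$z_k = (A/2)\,[\,2\cos^{2n}(\pi k/N) - 1\,]$ per axis with $n = 2$ by
default. Phase 0 is the designated end-exhale extreme and the accumulation
reference; because $\cos^4$ dwells off-centre, the time-averaged position
does not coincide with the mid-cycle phase, which is exactly why MidV
selection is non-trivial (for N = 10, n = 2 it returns phase 2, not 5).

**Displacement fields.** Analytic, not registered: the phase-$k$ field is
the centroid shift times a smooth spatial envelope. The envelope is exactly
1 in a plateau of radius $1.5 r_{GTV} + 5$ mm (tumour plus tracking margin
move rigidly — and a tracking plan can then follow its target exactly, which
the tracking-invariance test requires), decays as a Gaussian with
$\sigma = 3 r_{GTV}$, and is tapered smoothly to exactly zero in the
outermost 2% shell of the body (the chest wall does not breathe with the
tumour). Fields are therefore smooth, bounded by the trajectory amplitude,
and have known ground truth — the point of an analytic phantom; they do not
model sliding at the pleura, hysteresis, or inter-fraction baseline drift.

**Dose model.** Dose painting is geometric, not a transport calculation: a
cloud shaped to the PTV with maximum dose $D_{max} =$ prescription /
isodose-fraction (75% tracking, 80% fixed by default, the mid-points of the
clinically used 62–83% and 78–85% ranges) and a penumbra that crosses the
prescription isodose exactly at the PTV surface. The penumbra has two
Gaussian components: a sharp core (SD 3 mm tracking, 5 mm fixed) and a
broad scatter/peripheral component (fraction 0.25/0.2, width 6×/4× the
core SD). The broad component matters: penumbra in low-density lung is
substantially wider than in water and crossing beams deposit a dose bath,
and without it the normal-tissue Vx% shells are unrealistically thin —
thin enough that motion blur of the shell dominates every other
amplitude effect. The tracking cloud is the covering sphere of the PTV
(plus half a voxel of slack, so full coverage survives the trilinear
resampling of the warp); the fixed cloud is an ellipsoid fitted to the
PTV mask and rescaled so the prescription isodose covers 95% of the PTV
voxel centres — the standard clinical normalization, which also makes the
static-plan coverage 95.0% by construction.

**Cohort.** `sample_cohort()` draws GTV volumes log-uniformly over
0.6–77.9 cc and per-axis amplitudes uniformly over SI 1.0–22.5, AP 0.1–3.5,
LR 0.2–3.8 mm, rescaling the amplitude vector so the 3D motion lies in
2.1–22.8 mm; 2 in 14 patients are "central" lesions (48 Gy / 6 fx), the
rest peripheral (60 Gy / 3 fx). Prescription isodose is held at the
technique defaults across the cohort — sampling it per patient adds
cross-patient variance that has nothing to do with the motion mechanism
under study — while MU/Gy is sampled over the observed per-technique
ranges. Every quantity is reproducible from the seed, and each patient has
an index-derived substream so enlarging a cohort never reshuffles earlier
patients.

## Metrics

* **DVH** (`dvh`): the exact empirical distribution of member-voxel doses,
  unbinned. `dose_at_volume` (Dx%) uses the largest-dose-covering
  convention with linear interpolation between order statistics at the
  fractional rank (stated explicitly because TPS vendors differ); for 100
  voxels dosed 1..100 Gy, D99% = 2 Gy. `volume_at_dose` gives VxGy in % or
  cc.
* **Conformity** (`nci`): $nCI = (PI \times PTV)/TVIP^2$ with $PI$ the
  prescription-isodose volume restricted to the body (dose in air is not
  conformity), $TVIP$ the covered PTV fraction; 1 is ideal, larger is
  worse.
* **NTD2** (`ntd2_volume`): per-voxel linear-quadratic conversion
  $NTD_2 = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)$ with $d = D/n_{fx}$
  and $\alpha/\beta = 3$ Gy, used for the lung V20 constraint.
* **Normal-tissue shells** (`normal_tissue_shells`): absolute cc of
  body-minus-target receiving ≥ 80/50/30/10% of prescription. The pipeline
  subtracts one *common* volume (the uniform-5 mm tracking PTV) for both
  techniques: with technique-specific subtraction, the fixed technique's
  own margin ring — precisely the tissue its larger PTV sacrifices — is
  excluded from its shells, and the amplitude dependence of the comparison
  inverts. Comparing both accumulated doses on the same structures is also
  what makes paired differences meaningful. `compute_metrics()` defaults
  to the supplied PTV; the common-volume choice is the pipeline's and is
  recorded in its output.
* **van Herk margins** (`van_herk_margin`):
  $M = 2.5\,\Sigma + 1.64\,(\sqrt{\sigma^2 + (cA)^2 + \sigma_p^2} -
  \sigma_p)$ per axis, with breathing entering as a random blur of SD
  $c A$ ($c = 0.36$, the SD of the $\cos^4$ offsets relative to
  peak-to-peak amplitude) and penumbra SD $\sigma_p = 3.2$ mm. The cohort
  defaults $\Sigma = (2.0, 2.0, 2.5)$ and $\sigma = 2$ mm are illustrative:
  the per-patient setup/baseline errors behind published margins are not
  recoverable, so the recipe is validated structurally (zero at zero error,
  strictly monotone and sublinear in amplitude), not against printed
  millimetre values.
* **Delivery efficiency** (`beam_on_time`): beam-on time = (MU/Gy × total
  prescription) / dose rate (600 MU/min tracking, 400 fixed). This is the
  relation consistent with the packaged per-patient efficiency table for
  both schedules; the literal per-fraction variant is available with
  `per_fraction = TRUE`.

## Statistics

`wilcoxon_signed_rank` is the paired two-sided test: zero differences are
dropped (Pratt variant by flag) and for n ≤ 20 the p-value is exact,
computed from the conditional-on-ties null distribution of the signed-rank
statistic by a polynomial (subset-sum) enumeration over all $2^n$ sign
assignments; a 14-patient cohort is therefore always exact, which matters
when borderline p ≈ 0.05 results are interpreted. Above n = 20 a normal
approximation with tie and continuity corrections is used.
`spearman_rank` computes rho as the Pearson correlation of average ranks
with a t-approximation p (exact permutation p for n ≤ 10 by flag).
No multiple-testing correction is applied; exact p-values are reported and
interpretation is left to the analyst.

## The end-to-end pipeline

```{r pipeline, eval = FALSE}
report <- run_pipeline(run_config(n_patients = 14, seed = 1))
report$tests         # paired Wilcoxon, 4D tracking vs 4D fixed
report$correlations  # Spearman: 3D motion vs tracking-minus-fixed shells
```

Per patient: phantom and trajectory → PTVs (GTV + 5 mm; MidV GTV + van Herk
margin) → per-phase tracking and fixed doses → equal-weight accumulation to
end-exhale → metrics rows for the static (3D) and accumulated (4D)
evaluations → paired cohort statistics. The fixed technique's 3D row is
evaluated on the MidV geometry, its 4D row against the reference-phase
structures. A 14-patient default run takes about a minute on one core
(≈ 410k voxels × 10 phases × 2 techniques); unit tests use a coarser
phantom.

The mechanisms this reproduces, and which the acceptance tests assert, are:
motion degrades the fixed technique's PTV coverage and conformity (4D
coverage < 3D coverage and 4D nCI > 3D nCI for every patient with SI
amplitude > 5 mm); tracking maintains GTV D99% at or above prescription for
all patients; and the tracking-minus-fixed difference of the V80/50/30
normal-tissue shells correlates negatively with 3D motion — the larger the
motion, the more normal tissue the fixed technique's margin irradiates
relative to tracking.

## Numerical choices and degenerate inputs

Trilinear interpolation everywhere (dose warping, resampling); plain voxel
warping without energy/mass-congruent transfer, a known limitation of
equal-weight accumulation that this package shares deliberately with common
practice. MidV ties (e.g. a static trajectory) resolve to the lower phase
index with a 1e-9 mm tolerance so symmetric phases are not split by
floating-point noise. Empty masks are rejected for DVHs; an isodose that
misses the PTV makes nCI undefined and errors rather than returning
infinity. All-zero paired differences return p = 1 with a warning.
Geometries compare equal within 1e-6 mm.

## What passing tests do and do not show

The phantom has known ground truth by construction: rigid tumour motion,
smooth compactly supported fields, spherical targets, geometric dose
clouds. Passing tests therefore validate the *procedures* — warping,
accumulation, MidV selection, margins, metrics, statistics — and the
*direction and interplay* of the motion mechanisms, not clinical dose
accuracy. Real 4D CT data adds deformable (non-rigid) motion, registration
uncertainty, density heterogeneity, delivery-geometry effects
(e.g. under-couch beam exclusion, which this phantom's isotropic dose model
does not emulate — the anterior/posterior V10% asymmetry seen clinically is
out of scope), and interplay between MLC and organ motion (reported
elsewhere to be negligible for this regime). OAR near-maximum doses in the
phantom are small because the toy clouds have no patient-specific beam
paths; the D1% machinery is instead validated against counting oracles and
anchored on the packaged reference table.
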