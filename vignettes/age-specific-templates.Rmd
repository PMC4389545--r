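---
title: "Age-specific brain templates: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-specific brain templates: models, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automated tissue classification of T1-weighted brain MRI usually leans on
spatial tissue priors: probability maps, in a template space, of finding gray
matter (GM), white matter (WM), or the CSF-like "other matter" (OM) class at
each location. Priors built from young adults misrepresent older brains —
ventricles expand, deep gray structures are displaced, the cortical ribbon
thins — so segmentations of older subjects inherit a systematic bias.
`agetpl` implements the full counter-programme: build *age-specific* average
templates by iterative nonlinear registration and averaging, derive
age-specific tissue priors from per-subject partial volume estimates (PVEs),
and quantify with Dice overlap how much age-appropriate priors help, and how
segmentation quality decays as priors come from increasingly age-distant
templates.

Because the original multi-site cohorts (over a thousand scans) cannot ship
with a package, `agetpl` includes a first-class synthetic phantom module:
seeded, age-parameterized head volumes with exact ground-truth tissue maps
that every pipeline stage consumes. All acceptance-style claims are made — and
only made — on that synthetic world.

## The phantom world

A phantom is a set of concentric smooth shells defined in world millimetres
(scalp, skull, intracranial cavity of radius 52 mm; inside it a central
ventricle, a deep-GM ring, a WM shell, a cortical GM ribbon, and subarachnoid
CSF). The aging model drives the radii through the intracranial tissue
*fractions*:

* GM fraction: linear, `f_gm(age) = 0.50 + gm_slope * (age - 20)` with the
  default `gm_slope` chosen so the GM fraction falls by ~15% (relative)
  from age 20 to 89;
* WM fraction: quadratic with vertex at `wm_peak_age = 50`
  (`f_wm = 0.35 - 2e-5 * (age - 50)^2`), i.e. a slight rise to 50 and decline
  after;
* OM fraction: the remainder, split between the ventricle (a share growing
  from 0.30 at age 20 to 0.50 at 89) and subarachnoid CSF.

These coefficients are *conventions*, not estimates: the source material
states the qualitative trends but no effect sizes, so the defaults were chosen
once to be anatomically plausible and are not revisited. Given the fractions,
every boundary radius has a closed form, which is what the 2%
analytic-volume test checks.

Two design points deserve explanation:

* **The deep-GM ring.** Real ventricles are lined by deep gray matter
  (caudate, thalamus). Without it, the phantom's ventricle wall jumps from
  CSF (30) to WM (110), and the partial-volume voxels on that wall average to
  exactly the GM intensity (70) — a large artifactual "GM rim" that dominates
  any comparison of spatial priors. With the 3 mm ring the wall reads
  CSF → deep GM → WM, the masquerade disappears, and — importantly — the ring
  is exactly the structure whose outward displacement with ventricular
  expansion makes age-appropriate priors informative.
* **Noise `sigma = 8`** (on the pre-normalization scale where pure GM = 70,
  i.e. ~11 units after GM-peak norming to 100). This parameter stands in for
  *all* within-class intensity variability — scanner noise, biological
  heterogeneity, residual partial voluming — not just thermal noise. Class
  standard deviations fitted to real GM-normalized T1 data are typically
  8–15 units; a pure-thermal value (3–5) would make the likelihood nearly
  decisive at every voxel and priors irrelevant, which is not the regime the
  original study (or any real segmentation) operates in.

Per-case seeds are derived from a root seed by stable string hashing, so
cohorts are bit-reproducible. Boundary jitter (default 1.5 mm RMS) is a
smooth random directional field (linear and quadratic spherical monomials),
independent per subject.

What the phantom deliberately does **not** model: gyrification and sulcal
anatomy, subcortical nuclei as separate structures, MRI physics (no k-space,
Rician noise, or ringing), and multi-site protocol differences beyond a
smooth multiplicative bias field. Green tests therefore establish that the
pipeline machinery behaves correctly and that the age-prior logic works on a
geometrically honest but smooth stand-in — not that effect sizes transfer to
real cohorts.

## Preprocessing

The preparation chain is fixed as: brain extraction → bias correction →
provisional prior-free segmentation → GM-peak intensity standardization
(the order is not fully specified in the source procedure; this package fixes
and documents it).

* **Brain extraction** registers the head to an atlas head (rigid, 6-DOF),
  propagates the atlas brain mask through the inverse transform, and applies
  a one-voxel morphological closing. The surface-refinement passes of the
  original FSL chain are out of scope; on phantoms the single pass reaches
  Dice ≥ 0.95 against ground truth.
* **Bias correction** is a simplified N4-style scheme: iterate
  {classify the corrected intensities into three 1D k-means classes, fit a
  low-order 3D polynomial to the within-class log-residuals (trimming the
  largest 30% of residuals, which are partial-volume voxels), update the
  field} until the field changes by < 0.1%. The polynomial degree comes from
  the `control_spacing` (~one degree per control spacing across the field of
  view, capped at 4). N4's histogram sharpening is not reproduced; only the
  smooth-multiplicative-correction behaviour matters downstream. On a
  noise-free 64^3 phantom with a known exponential-quadratic bias the field
  is recovered within ~1% RMS.
* **GM-peak norming** averages the intensity of voxels whose GM PVE ≥ 0.999
  ("PVE of 1.0" up to float tolerance) and rescales the volume so that this
  mean is exactly 100. Because the package's PVE is a posterior probability
  (below), "pure" voxels are only approximately pure, and the post-norm
  histogram mode lands within ~1% of 100 rather than exactly on it.

## Segmentation

`segment_em()` is a three-class Gaussian-mixture EM on in-mask intensities;
the PVE is the final posterior (soft assignment). The FAST mixel/PV model is
deliberately not reproduced: downstream analyses only do PVE arithmetic, and
posteriors satisfy the same contracts (values in [0,1], per-voxel sum 1 inside
the mask). Design choices:

* Prior-free initialization: deterministic 1D k-means centers (percentile
  seeded), equal SDs; classes are reported in increasing-mean order, which on
  T1 contrast is OM < GM < WM. (Plain percentile initialization proved
  fragile — two seeds can land in the GM basin.)
* `a_priori` usage seeds the responsibilities with the prior maps and then
  continues with global mixing weights only — priors-at-initialization, the
  "FAST -A" analogue. `a_posteriori` keeps the prior maps in every E-step.
  A prior of exactly zero annihilates the posterior exactly.
* Convergence: relative log-likelihood change < 1e-6, cap 200 iterations;
  SD floor `max(1e-3, 1e-4 * range)` so noise-free inputs cannot collapse.
* Optional Potts/ICM smoothing (`mrf_beta`, default 0 = off) because the
  original FAST regularization settings are unstated; EM log-likelihood
  monotonicity is only guaranteed at `mrf_beta = 0`.
* Hard labels: per-voxel argmax, ties to the lowest class in OM < GM < WM
  order, background 0.

A property worth knowing: with unconstrained per-class variances and very low
noise (sigma ≲ 3 at 2–4 mm voxels), the GM class inflates its variance and
absorbs the partial-volume continuum between CSF and WM, *lowering* GM Dice
below what moderate noise gives. This is a known Gaussian-mixture pathology
(FAST's explicit PV model exists partly to avoid it). The noise-robustness
property is therefore asserted on sigma in {5, 10, 15}, where Dice decays
monotonically.

## Registration

Two backends behind one contract:

* `register_rigid()`: 6-DOF Nelder-Mead on the SSD metric, two stages
  (smoothed/strided, then full resolution). Self-registration returns the
  identity within 0.1 mm / 0.1 degrees; known 3 mm translations are recovered
  within 0.2 mm and 5-degree rotations within 0.5 degrees. A `coarse` quality
  mode (first stage only) is used for bulk prior mapping where sub-voxel
  precision is unnecessary.
* `register_deformable()`: diffeomorphic-demons style. Rigid pre-alignment
  (the cohorts here have no global scale differences, so a full 12-DOF affine
  stage is unnecessary), then a 3-level pyramid (4x/2x/1x) whose per-level
  iteration counts mirror the published coarse/medium/fine progression
  (50x0x0, 50x50x0, 50x50x50). Each iteration computes the demons force,
  caps it at one voxel, smooths it (fluid sigma 1 voxel), exponentiates it by
  scaling-and-squaring so each increment is a small diffeomorphism, composes,
  and smooths the accumulated field (diffusion sigma 0.7 voxel). The final
  field folds the pre-alignment in; the inverse is computed by fixed-point
  iteration (max 20 sweeps) to a 0.2-voxel composition tolerance, and the
  field is replaced by zero if it would do worse than affine-only (metric
  non-degradation guarantee).

Both displacement fields live on the fixed/template grid in world mm. This is
a simplification (a true inverse lives on the moving grid); it is adequate
here because all volumes share closely matched fields of view, and the
composition tolerance is asserted rather than assumed.

## Template construction and priors

`build_template()` is the classic iterative average: rigidly align everything
to an initial reference, average (plain arithmetic mean, non-normalized —
matching the published averaging step), then iterate {deformably register
every subject to the current average with the scheduled resolution, warp,
re-average} while recording the RMS difference between successive averages.
"Leveling" of the RMS curve is undefined in the source; here it is a relative
RMS change < 5% (default `max_iter` 6). Priors are built by forward-warping
each subject's PVE maps with the final-iteration transforms ("final" taken
literally) and averaging per class, clamped so the per-voxel class sum stays
at most 1.

Measuring the template itself deserves a caveat: prior-free EM on an average
image overstates GM (the averaging blur widens the GM-intensity band and the
variance-absorption effect lets the GM class claim it), by ~10% even at 2 mm
with strong schedules. The template-size checks therefore segment the
template with its own cohort priors applied a posteriori, which lands within
~2% of the cohort-mean ground truth. Relatedly, aging-trend fits on EM-based
volumes recover the WM vertex well but give a GM slope ~5–9% shallower than
the generator's (the GM bias varies slightly with age); the trend-recovery
checks use ground-truth volumes and the bias is reported here instead of
being hidden in a tolerance.

The role of the external standard-space atlas ("MNI") is played by an
internally built reference set: the young-adult (20–24) template and priors
constructed with the same pipeline. The reference-based ("MNI"-like) prior
sets are produced by re-segmenting every subject with the reference priors
applied a priori, then averaging those PVEs in template space.

## Evaluation

* Dice is `2|A ∩ B| / (|A| + |B|)` on hard labels per tissue; the both-empty
  case is defined as 1 (and logged) — real data never produces it. A soft
  Dice on PVEs is provided for inspection but not used in any claim.
* The eleven-variant harness reproduces the published comparison grid:
  prior-free; reference priors a priori; image-averaged priors a priori and a
  posteriori for the young-adult, age-matched five-year, and age-matched
  ten-year templates; and reference-averaged priors a posteriori for the same
  three. Priors are mapped into subject space by registering the subject to
  the owning template. The default mapping is rigid, matching standard FSL
  practice of supplying FAST priors through a FLIRT transform; a deformable
  mapping is available. On this phantom's smooth geometry a fine-scale
  deformable mapping absorbs essentially all age-related shape difference
  (real cortical anatomy would not be fully absorbable), which collapses the
  age-appropriate vs young-adult contrast — one more reason the rigid mapping
  is the default for the claims.
* The age-offset analysis follows the published design: four subjects per
  five-year group (56 in the full design), segmented with the age-appropriate
  five-year priors (offset 0, the proxy standard) and with every other
  group's priors; Dice of each offset segmentation against the offset-0
  segmentation, per tissue. Offset-0 rows are excluded from output by default
  (they are identically 1) but can be included.
* The published mixed 14 x 26 ANOVA is replaced by one-way ANOVAs plus a
  Spearman trend statistic on |offset| vs Dice: the original post-hoc
  machinery is unnamed and its degrees-of-freedom structure is not
  reproducible without the raw data.
* Volumetrics: per-class volume is the PVE sum times voxel volume; the trend
  report tabulates five-year-group means with standard errors and fits a
  linear age model to GM and a quadratic to WM, whose vertex estimates
  `wm_peak_age`.

## What the claims mean here, and known limitations

The headline scientific claim — age-appropriate image-averaged a-posteriori
priors beat young-adult priors, which beat raw reference priors — reproduces
in this synthetic world in its first and strongest link: age-appropriate
priors beat young-adult priors (and beat reference-only priors) with paired
one-sided tests over 20 aged phantoms. The middle link (young-adult
a-posteriori ≥ reference-only a-priori) does **not** reproduce, and the
package keeps that assertion failing rather than weakening it: in the
original study the reference-prior-only method collapses because FAST's
initialization-sensitive PV/MRF machinery never recovers from mismatched
priors, whereas this package's plain EM (priors-at-initialization only)
converges to the prior-free optimum — so reference-only segmentation here is
simply ordinary segmentation, and actively wrong young-adult spatial priors
can score below it. This is a faithful consequence of the stated design
decisions, documented rather than patched.

Other limitations worth stating plainly: the phantom's smooth spherical
geometry makes deformable registration unrealistically effective; posterior
PVEs are not mixel-model PVEs, so "pure" voxels are only approximately pure;
tests and the acceptance report run at desk scale (32^3–64^3 voxels,
shortened demons schedules) rather than the 1 mm/50-iteration production
scale, trading registration polish for runtime while leaving every contract
unchanged.
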