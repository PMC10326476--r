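---
title: "Methods: universal tau-PET masks and the CenTauR z scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: universal tau-PET masks and the CenTauR z scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centaurz)
```

## Scope and assumptions

`centaurz` is a pure quantification layer for tau-PET volumes that are
*already* spatially normalized to a common template grid. It performs no
registration, resampling, motion correction or partial-volume
correction: every multi-image operation checks `grids_compatible()`
(shapes identical, affines elementwise within 1e-3 mm) and fails fast
on a mismatch rather than silently interpolating. Grid geometry is
treated as data carried by each NIfTI file, not as an assumption — any
shape and voxel size works, provided one voxel axis is aligned with the
world left-right axis (needed only for symmetrization).

Missing voxels (NaN, common at the cerebellar lower edge and
out-of-field regions) are excluded from every mean and from mask
membership; `read_volume()` counts and warns about them.

## The reference region

SUVR needs a reference with stable, tau-free uptake. The cerebellar
cortex qualifies except for its upper slices (vermis off-target
binding) and its lowest slices (partial volume, low axial sensitivity,
out-of-field scatter). `build_reference_region()` therefore keeps only
cerebellar voxels whose world z lies in `[-47, -37]` mm. Two
interpretation choices are deliberate:

* the bounds are **world-space millimetres** computed through the
  affine, not slice indices — the template-space convention expresses
  cerebellar extent in mm, and it makes the operation invariant to
  voxel size;
* the bounds are **inclusive**: the excluded regions are strictly
  above -37 and strictly below -47, so the boundary slices belong to
  the reference.

Both bounds are arguments, so a site whose distributed masks disagree
can reconfigure them.

## Mask construction

For each tracer, group-mean images of CU Aβ− and AD Aβ+ scans are
averaged voxelwise (`mean_image()`, missing voxels dropped per voxel)
and subtracted (`difference_image()`). The tracer-specific mask keeps
voxels whose difference is at least a fraction (default 1/3) of the
difference summarized over an inferior temporal anchor mask
(`tracer_mask()`). Design choices:

* The anchor summary is the **mean** over the anchor mask. A single
  representative value or a median would also be defensible; the mean
  is the standard summary and the median remains available via
  `summary = "median"`.
* The comparison is `>=` (ties kept). Ties are measure-zero in real
  data; including them makes the operation deterministic and keeps the
  limit case `fraction -> 1` well defined. The absolute threshold used
  is attached to the result and reported, for provenance.
* `tracer_mask()` is antitone in `fraction` — raising the fraction can
  only shrink the mask — and refuses to run when the anchor shows no
  AD>CU contrast (nonpositive anchor mean), since a threshold derived
  from noise would be meaningless.

The universal mask is `symmetrize(intersect(tracer masks) ∩ GM)`, in
that fixed order: intersection across tracers first, gray-matter
restriction second, left-right symmetrization last. Gray-matter
probability maps are binarized at > 0.5 (`read_mask()` default).
"Fusion" of the mask with its mirror image is the **union**: the goal
of symmetrization is to remove hemispheric asymmetry of tau topography,
and union is the only monotone choice that never discards observed
signal. Reflection maps each voxel across the world plane x = 0 with
half-up rounding to the nearest voxel column; half-up (rather than
round-half-even) keeps the index map an involution when the midplane
bisects a voxel column, which is what makes `symmetrize()` idempotent
on any grid. Subregion masks are intersections of anatomical extents
with the universal mask; the four subregions are not required to be
disjoint (a meta-temporal composite legitimately contains the mesial
temporal region), so no disjointness is asserted anywhere.

Per-tracer masks are *not* individually symmetrized — symmetrization
happens once, on the universal mask.

## The CenTauR z scale

For a tracer/ROI pair, CTRz is the z-score of SUVR with respect to the
CU Aβ− calibration population: `calibrate_scale()` returns
`slope = 1/σ`, `intercept = -μ/σ`, so `CTRz(μ) = 0` and
`CTRz(μ + σ) = 1` identically. σ is the **sample** (n−1) standard
deviation — the standard choice for cohort z-scores — with the
population variant available via `sd_type`. CTRz is affine on all of
ℝ: values below the CU mean are negative and are never clamped,
because "below the calibration mean" is meaningful information.

The six published tracer × five ROI conversions ship in
`inst/extdata/centaur_scales.csv` (columns tracer, roi, slope,
intercept, pipeline, source), with intercepts stored **signed**; the
printed "a·x − b" dialect was transcribed once into the data file and
is never parsed at runtime. `published_scales()` and `ctrz_scale()`
are the only access paths, so the CSV is the single source of truth.
The schema carries a `pipeline` key so alternative coefficient sets
(e.g. from a different normalization pipeline) can be loaded without
code changes.

ROI SUVR is the **ratio of means** (mean target / mean reference), not
the mean of voxelwise ratios. Because the reference summary is a
scalar the two coincide, but the definition is pinned to prevent
drift; the same scalar-divisor property gives the parametric-image
identity `mean(ctrz_image over ROI) == suvr_to_ctrz(compute_suvr(ROI))`
(tested to 1e-9). For voxelwise (parametric) CTRz images the
temporo-parietal equation is the suggested default scale for a global
transformation.

## Classification

Tau positivity is `CTRz > θ` with θ = 2 fixed a priori, and **strict**:
a value exactly at the threshold counts negative, matching the "higher
than 2" phrasing of the operating point and making the boundary
deterministic. The topographic subtype is the exhaustive 2×2 partition
on (mesial-temporal, meta-temporal) CTRz at the same threshold:

| mesial > θ | meta > θ | label |
|---|---|---|
| no  | no  | tau_negative |
| yes | no  | limbic_predominant |
| no  | yes | hippocampal_sparing |
| yes | yes | typical |

The tau-negative and limbic-predominant cells are the explicitly
stated rules; the hippocampal-sparing cell is the completion of the
2×2 logic (cortical signal without mesial signal), chosen here as the
package's quantitative definition — visual hippocampal-sparing reads
("no or minimal MTL signal") are not implemented. ROC-style threshold
optimization is out of scope; θ is a parameter, not a fitted quantity.

## The phantom generator

`phantom_spec()`/`simulate_cohort()` generate template-space cohorts
with known ground truth. The default grid is 32×38×32 at 4 mm (a
downscaled normalized-space grid; the conventional 91×109×91 at 2 mm
works identically and is just larger). `make_layout()` places
mirror-symmetric boxes in world coordinates: an inferior cerebellar
slab spanning z well below −20 mm (so the −47..−37 mm reference slab
is nonempty), four pairwise-disjoint cortical regions, an inferior
temporal anchor nested inside the meta-temporal region (so the
AD-vs-CU anchor contrast exists whenever cortical regions are
elevated), and a gray-matter envelope containing all cortical regions
and disjoint from the cerebellum.

Signal model per subject: each cortical region's true SUVR is drawn
`Normal(cu_suvr_mean, cu_suvr_sd)`, plus `ad_effect` in the regions its
subtype elevates (limbic-predominant: mesial only; hippocampal-sparing:
the cortical regions only; typical: all; tau-negative: none). The image
is `reference_level × (background + region SUVR)` with additive
Gaussian voxel noise and optional isotropic Gaussian smoothing (FWHM in
mm; separable convolution with edge renormalization). Defaults:

* `cu_suvr_mean = 1.0`, `cu_suvr_sd = 0.1` — the CU population implied
  by the published MK6240-like conversions (slope ≈ 10 means σ ≈ 0.1;
  intercept/slope ≈ 1 means μ ≈ 1);
* `ad_effect = 1.0` (mesial, meta), `0.9` (temporo-parietal), `0.6`
  (frontal) — a meta-temporal elevation of one SUVR unit puts the AD
  group near CTRz 10, inside the reported AD range, with the frontal
  region deliberately weaker to mirror its lower sensitivity;
* `noise_sd = 0.1` uptake units (10% of the reference level),
  `smoothing_fwhm = 0` so unit tests are exact.

Noise is additive Gaussian before smoothing. Real PET noise is
Poisson-seeded, spatially correlated, and accompanied by anatomy,
off-target binding (choroid plexus, meninges, vermis) and
scanner-specific resolution; the phantom emulates none of that. What
passing tests on the phantom show is that the *arithmetic* of the
framework — mask recovery, scale calibration, threshold classification
— behaves correctly under controlled first and second moments; they do
not certify performance on real scans.

All cohort-level randomness flows from the single `seed` argument of
`simulate_cohort()`; `simulate_subject()` draws from R's current RNG
stream, per normal R practice.

## Numerical choices and degenerate inputs

* Grid compatibility tolerance: 1e-3 mm elementwise on the affine;
  write→read round-trips preserve values bitwise and affines within
  1e-6.
* Empty masks are rejected wherever a mean is taken; `dice()` of two
  empty masks is an error (undefined), while `mask_intersect()` may
  return an empty mask since downstream users validate.
* Calibration requires n ≥ 2 and nonzero variance; a fully noiseless
  phantom therefore cannot be run through cohort calibration (its CU
  SUVRs are constant), which is intentional.
* Zero-variance, nonpositive-reference, no-contrast-anchor and 4-D
  inputs all raise errors naming the problem rather than propagating
  NaN.

## Problem sizes in the test suite

The suite runs on the default 32×38×32 phantom grid with cohorts of
3–16 subjects per group for mask-recovery checks (10 seeds for the
noisy case), 100 per group for the classification operating point, and
n = 200 with a 500-replicate sweep for calibration parameter recovery
— sizes chosen so each property is measured with comfortable margin
while the whole suite stays fast.

## Known limitations

* Spatial normalization quality is assumed, never checked; visual QC
  of registration is a human procedure outside this package.
* The packaged coefficients apply to scans processed with the pipeline
  they were derived from; scans from a different normalization
  pipeline need recalibration (`calibrate_scale()` on a local CU Aβ−
  cohort).
* Longitudinal reproducibility of the scale is untested here.
* The anatomical extents of the four subregions are data (masks
  supplied by the user or the layout generator), not geometry encoded
  in this package.
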