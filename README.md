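# centaurz

Standardized tau-PET quantification on the universal CenTauR scale.

Tau PET tracers (flortaucipir/FTP, MK6240, PI2620, PM-PBB3, RO948, GTP1)
differ in binding affinity, kinetics and off-target signal, so raw SUVR
values are not comparable across tracers or centers. `centaurz`
implements a harmonization framework for scans already normalized to a
common template space:

- **Mask construction** — tracer-specific tau masks from group-mean
  images (AD Aβ+ minus CU Aβ− difference image, thresholded at a
  fraction of its inferior temporal mean), intersected across tracers,
  gray-matter restricted, and left-right symmetrized into a universal
  cortical tau mask, with subregions (mesial temporal, meta temporal,
  temporo-parietal, frontal) carved inside it. Mask agreement is
  measured with the Dice index `2|A∩B| / (|A|+|B|)`.
- **Reference region** — cerebellar cortex restricted to template
  slices `-47 mm ≤ z ≤ -37 mm`, avoiding vermis off-target binding
  above and edge artifacts below.
- **CenTauR z-scores (CTRz)** — per tracer and ROI, the affine
  conversion `CTRz = SUVR/σ − μ/σ`, where μ and σ are the mean and SD
  of the cognitively-unimpaired amyloid-negative (CU Aβ−) calibration
  population. The six published tracer × five-ROI coefficient pairs
  ship as a packaged table; scales can also be calibrated from any CU
  cohort. Voxelwise CTRz parametric images use the same conversion
  (temporo-parietal equation suggested for global transforms).
- **Classification** — tau positivity at CTRz > 2 and the 2×2
  topographic subtype rule on mesial- vs meta-temporal CTRz
  (tau-negative / limbic-predominant / hippocampal-sparing / typical),
  with accuracy, sensitivity, specificity and prevalence helpers.
- **Phantom cohorts** — a synthetic template-space generator with known
  per-region ground truth, so the whole pipeline is testable without
  any scan data.

## Worked example

```r
library(centaurz)

## published conversion for 18F-MK6240 in the meta-temporal ROI
scale <- ctrz_scale("MK6240", "meta_temporal")
scale
#> tracer_scale [MK6240, meta_temporal, CL-SPM]: CTRz = 9.36 * SUVR - 10.6

suvr <- c(1.05, 1.40, 2.10)          # three subjects' meta-temporal SUVR
round(suvr_to_ctrz(suvr, scale), 2)
#> [1] -0.77  2.50  9.06
tau_positive(suvr_to_ctrz(suvr, scale))   # CTRz > 2
#> [1] FALSE  TRUE  TRUE
```

The first subject sits below the CU Aβ− mean (negative CTRz), the
second is just above the positivity threshold, and the third carries an
AD-like tau burden about nine CU standard deviations above the
calibration mean.

End to end on a synthetic cohort (100 CU Aβ−, 100 AD Aβ+; images are
simulated, SUVR measured against the sub-cerebellar reference, scales
calibrated on the CU subjects):

```r
co <- simulate_cohort(phantom_spec(), n_cu = 100, n_ad = 100, seed = 7)
m <- diagnostic_metrics(tau_positive(co$table$ctrz_meta_temporal),
                        co$table$group == "AD")
c(accuracy = m$accuracy, sensitivity = m$sensitivity,
  specificity = m$specificity)
#>    accuracy sensitivity specificity
#>       0.985       1.000       0.970

table(tau_subtype(co$table$ctrz_mesial_temporal,
                  co$table$ctrz_meta_temporal))
#>        tau_negative  limbic_predominant hippocampal_sparing
#>                  95                   2                   3
#>             typical
#>                 100
```

The simulated AD group lands at meta-temporal CTRz ≈ 8–12, and the
threshold-2 rule separates the groups with high accuracy; the few CU
subjects crossing a single regional threshold by chance are labelled
accordingly.

A thin command-line wrapper over the same functions is in
`inst/cli/centaur.R` (`dice`, `refregion`, `quantify`, `calibrate`,
`parametric`, `classify`, `simulate`).

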