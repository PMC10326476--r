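Package: centaurz
Title: Universal Tau-PET Quantification on the CenTauR Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for standardizing tau-PET quantification across
    radiotracers: construction of universal and regional cortical tau
    masks from group-mean images, SUVR computation against a
    slice-restricted sub-cerebellar reference region, conversion of SUVR
    to the universal CenTauR z-score (CTRz) scale per tracer, voxelwise
    CTRz parametric images, and CTRz-threshold tau-positivity and
    topographic-subtype classification. Includes a synthetic phantom
    cohort generator with known ground truth so the full pipeline is
    testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
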