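Package: bbbleak
Title: Blood-Brain Barrier Leakage Mapping and Cohort Analysis for Sparse DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying subtle blood-brain barrier (BBB) leakage from
    sparsely sampled dynamic contrast-enhanced MRI and for relating leakage to
    blood pressure at cohort level. Converts T1 maps and dynamic signals to
    gadolinium concentration, fits voxelwise Patlak graphical models (leakage
    rate Ki and plasma volume fraction vp) against a vascular input function,
    summarizes leakage maps over tissue regions of interest with percentile
    outlier trimming, scores hypertension status, blood-pressure subgroups and
    cerebral small vessel disease burden, and runs the adjusted regression,
    subgroup ANOVA/Tukey and pooled-group comparisons of a hypertension-BBB
    study design. Includes synthetic phantom, vascular input function and
    cohort generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
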