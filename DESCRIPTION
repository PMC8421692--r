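Package: awaremap
Title: Memory Awareness and Neurodegeneration Mapping Across the
    Alzheimer's Clinical Continuum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying subjective memory decline (SMD)
    across the Alzheimer's clinical continuum. Computes age-, sex- and
    education-adjusted normative w-scores and the delta memory-awareness
    index (objective memory w-score minus reversed SMD w-score), compares
    scores between clinical groups (ANOVA with Tukey-Kramer post hoc tests,
    chi-square tests on delta-sign proportions), fits mass-univariate
    voxelwise regressions of neurodegeneration maps on the SMD w-score per
    clinical group and in interaction with global cognition (MMSE), and
    performs cluster-extent inference with a Monte-Carlo-derived minimum
    cluster size at a voxelwise p < 0.005 cluster-forming threshold. A
    seeded synthetic-data generator emulates cohort score distributions and
    plants stage-dependent, opposite-sign voxelwise effects so the full
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
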