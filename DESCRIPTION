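Package: fagap
Title: Voxel-Based FA Group Contrasts with Tiered Cluster Inference and
    Gap-Based Subgrouping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for voxel-based group comparison of fractional
    anisotropy (FA) maps in a shared stereotaxic space. Implements
    mass-univariate two-sample t contrasts, cluster-extent thresholding
    with an edge-sharing contiguity rule, tiered Bonferroni correction of
    peak voxels over a priori areas of evaluation, permutation validation
    of cluster-mean differences, a laterality index, a gapping analysis
    that detects breaks in the distribution of per-subject cluster-mean FA
    values with Monte-Carlo calibration, subgroup re-contrasts against
    individually matched controls, and Bonferroni-corrected symptom
    comparisons between subgroups. Includes a synthetic-cohort generator
    so the full pipeline can be exercised and validated without access to
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
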