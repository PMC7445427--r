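Package: neurocascade
Title: Longitudinal Symptom Cross-Lag, Brain-Wide Association, Mediation
    and Imaging Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage inference cascade for linking two longitudinal
    symptom streams to brain structure and gene expression: cross-lagged
    panel models with and without random intercepts estimated by full
    information maximum likelihood in a RAM formulation; family-aware
    multilevel block permutation inference; voxelwise gray-matter
    association with permutation cluster-level familywise error
    correction and cluster-overlap logic; bootstrap mediation of the
    brain to mediator to outcome pathway, including a voxelwise mediation
    map; and partial least squares association of a mediation map with
    spatially sampled gene expression, with permutation component
    selection and bootstrap gene z scores. A synthetic-data module
    generates family structures, panels, voxel image studies and
    expression matrices with known ground truth so every stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    metafor,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics
Config/testthat/edition: 3
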