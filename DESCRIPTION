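Package: psdconn
Title: Lesion-Aware Resting-State Connectivity Analysis for Post-Stroke
    Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise degree-centrality hub mapping, seed-based functional
    connectivity and group inference for three-group (healthy control,
    nondepressed stroke, post-stroke depression) resting-state fMRI designs.
    Includes lesion-aware preprocessing (hemisphere flipping, enantiomorphic
    filling, Friston-24 nuisance regression, hemodynamic time-shift
    correction, ideal band-pass filtering), Benjamini-Hochberg FDR with
    cluster-extent control, a three-group specificity conjunction for
    data-driven seed selection, Spearman brain-behavior association with
    Bonferroni control, ridge regression with leave-one-out cross-validation
    for depression-severity prediction, and a seeded synthetic cohort
    generator with known injected hub effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
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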