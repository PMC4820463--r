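Package: plastEC
Title: Evolutionary Search for Plastic Sub-Regional Pairs in Longitudinal
    fMRI Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects statistically significant positively and negatively
    plastic sub-regional pairs between two investigator-defined regions of
    interest across two BOLD-fMRI sessions. Voxel-wise Pearson correlations
    are thresholded by false discovery rate and binarized into per-session
    connectivity matrices; an evolutionary search over indirectly encoded,
    spatially connected voxel sub-regions then maximizes a binomial-test
    z-score of the change in edge count between sessions, recursing with
    edge blocking until no significant pair remains and applying Bonferroni
    correction. Includes ROI-averaging and total-edge-count baselines,
    subject-level plasticity estimates, run-to-run reliability metrics
    (Sorenson-dice, adjusted Rand index, voxel-pair consistency), and a
    synthetic-data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
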