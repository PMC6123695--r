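Package: fmrirep
Title: Split-Half Replicability Analysis of Task-fMRI Group Maps
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pseudo-replicate (split-half) resampling machinery for estimating
    the replicability of task-fMRI group-level statistic maps as a function of
    sample size. Provides a synthetic multi-subject dataset generator with
    controllable within- and between-subject variability, a one-sample t-to-z
    group model, repeated disjoint P/Q participant splits with nested
    sample-size prefixes, Gaussian-random-field cluster-extent and
    proportion-based thresholding, sign-sensitive voxel/cluster/peak
    similarity statistics, smoothness-matched null map simulation, and an
    orthogonalized "measurables" regression relating data properties to
    replicability, with MAP shrinkage aggregation across tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
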