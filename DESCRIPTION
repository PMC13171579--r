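Package: lfpadditivity
Title: Additivity Analysis of Multi-Site Stimulation Effects on LFP Band Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how unilateral, bilateral and multi-target
    deep-brain-stimulation conditions modulate local field potential (LFP) band
    power across a network of intracranial recording regions, and for classifying
    the interaction of combined stimulation as additive, sub-additive or
    super-additive on the additive scale. Includes a synthetic-data generator with
    planted effect structure and ground-truth interaction classes, a preprocessing
    chain (bipolar re-referencing, anti-aliased decimation, epoch segmentation),
    bump-wavelet time-frequency power estimation with pre/post band averaging,
    a deterministic edge-artifact screen, a sparse REML mixed-model engine with
    cluster-bootstrap percentile inference and Benjamini-Hochberg correction,
    and a decision-tree model predicting interaction class from stimulation,
    region and band features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    rpart,
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
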