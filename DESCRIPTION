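Package: actmap
Title: Brain-Wide IEG Activation Mapping and Fiber Photometry Response Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two linked analyses of neuronal-activity experiments in
    mice. First, brain-wide immediate early gene (IEG) cell-count tables
    (animals by parcellated brain regions) are z-scored, classified between
    treatment groups with a deterministic soft-margin linear support vector
    machine, and the classifier weights are transformed into forward-model
    activation patterns (A = Sigma_x W Sigma_s^-1) that nominate the brain
    region driving each discrimination; labelled insular-cortex cells are
    binned along the anteroposterior axis relative to bregma. Second, fiber
    photometry fluorescence traces are baseline-corrected with adaptive
    iteratively reweighted penalized least squares (airPLS), z-scored to a
    designated home-cage baseline period, investigation events are filtered to
    nonsequential contacts, and contact-evoked responses are quantified with
    paired and rank-correlation statistics. Seeded synthetic-data generators
    emulate every input with recoverable ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
biocViews: Software, Classification, Preprocessing, SystemsBiology
Config/testthat/edition: 3
RoxygenNote: 7.3.3
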