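Package: salientsort
Title: Salient-Feature Spike Sorting with Window Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for training and emulating a hardware-friendly
    extracellular spike sorter. Implements discriminative feature
    selection driven by an exponential class-discrimination index and a
    per-feature class-saliency statistic (with its geometric-mean and
    homogeneity decomposition), multi-label window discrimination for
    online classification, unsupervised k-means/silhouette labeling of
    training spikes, chance-level-independent evaluation metrics with a
    Gaussian naive Bayes reference classifier and static-feature
    baselines, and a bit-accurate fixed-point emulator of the on-implant
    online sorter including its register-bank memory budget. A built-in
    synthetic-data generator produces labeled extracellular spike
    waveforms and continuous traces for testing the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
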