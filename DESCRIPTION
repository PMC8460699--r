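Package: wsimil
Title: Self-Attention Multiple-Instance Learning for Slide-Level Genomic
    Label Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Weakly supervised prediction of binary genomic labels (gene
    point mutations, copy-number alterations, pathway activity) from
    whole-slide histopathology images. Slides are tiled, background tiles
    are filtered by a mean-intensity rule, tumor tiles are selected by
    k-means clustering with a manual-refinement hook, and tiles are color
    normalized by a slide-level mean/standard-deviation affine map. Tile
    features from a pluggable frozen extractor form one bag per patient;
    a multilayer perceptron with a self-attention layer aggregates the
    bag into a slide-level prediction trained with cross-entropy.
    Includes pathway-activity label derivation from expression or
    copy-number tables with oncogene/suppressor weights, patient
    splitting, AUC with bootstrap confidence intervals, frozen-layer
    transfer fine-tuning, attention weight-map visualization, and a
    synthetic-data generator with planted ground truth for offline
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
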