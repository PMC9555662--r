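Package: panelreduce
Title: Computational Panel Reduction for Multiplex Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing reduced marker panels for multiplex
    immunofluorescence (CyCIF) imaging and for assessing how much of the
    full panel's information a reduced panel retains. Implements four
    panel-selection strategies (intensity-correlation scoring over all
    candidate panels, self-expressive interaction-map scoring, encoder
    gradient importance ranking, and seeded random ordering) together with
    a 1-to-1 intensity-substitution baseline; a multi-encoder variational
    autoencoder that imputes the full panel's single-cell images from the
    reduced panel's channels; evaluation metrics (per-marker Spearman
    correlation, structural similarity, normalized mutual information of
    cluster labels with cluster matching); technical-noise simulators
    (Gaussian blur, salt-and-pepper, segmentation-mask perturbation) that
    contextualize imputation error; and a synthetic single-cell image
    generator with planted marker redundancy for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    igraph,
    cluster,
    optparse,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
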