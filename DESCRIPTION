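Package: histex
Title: Spot-Level Gene Expression Prediction from H&E Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts spot-level gene expression from hematoxylin-and-eosin
    stained histology images supervised by spatial transcriptomics data.
    Provides readers for per-section spatial transcriptomics data (image,
    spot coordinates, counts matrix, gene-symbol mapping), Vahadane-style
    sparse non-negative stain separation and normalization with luminosity
    standardization, gene and spot filtering, patch extraction with
    white-pixel exclusion, a trainable convolutional expression model with a
    main head for the top-expressed genes and an auxiliary head for the
    remainder under a lambda-weighted combined loss, patient-level
    cross-validation, per-gene correlation-based evaluation, and expression
    overlay rendering. A fully synthetic data generator with a known
    image-to-expression relationship makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
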