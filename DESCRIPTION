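Package: ExpertDT
Title: Pathologist-Guided Hierarchical Tile Classification for Renal Cell
    Carcinoma Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tile-based classification of renal cell carcinoma subtypes
    (clear cell, papillary, chromophobe, oncocytoma) from raster
    histology images. Implements a pathologist-designed tree of binary
    classifiers (tumor/not-tumor root, super-label node, differential
    leaves), single-pass spatial majority-vote label smoothing over the
    tile grid, a per-patient node-pruning rule driven by super-label tile
    imbalance, and patient-level majority voting, together with balanced
    accuracy and multiclass Matthews correlation evaluation. A seeded
    synthetic texture cohort generator with controllable hierarchical
    class separability allows the full pipeline to be trained, ablated
    and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
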