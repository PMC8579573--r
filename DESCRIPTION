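Package: amyloscan
Title: Amyloidogenic Region Prediction from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts amyloidogenic (hotspot) regions in proteins from
    sequence alone. Hexapeptides are encoded with Type 2 (series
    correlation) pseudo amino acid composition and tripeptide
    composition; discriminative tripeptides are selected by a
    binomial-distribution confidence score; a random-forest classifier
    trained on labeled hexapeptides scores a sliding hexapeptide window
    along each protein, and window calls are aggregated into per-residue
    hotspot masks and maximal regions. Includes per-residue evaluation
    metrics (accuracy, sensitivity, specificity, balanced accuracy Q,
    Matthews correlation), ROC/AUC, Friedman plus Nemenyi multi-method
    comparison, and a synthetic-data generator with tunable planted
    signal so the whole pipeline can be exercised without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    pROC,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
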