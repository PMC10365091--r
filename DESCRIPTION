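Package: gazemil
Title: Label-Specific Eye-Tracking Annotations for Weakly Supervised
    Lesion Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts eye-tracking data recorded during radiology report
    dictation into label-specific localization annotations, and uses them
    to supervise a grid-based chest radiograph classifier. Fixations are
    associated with dictated label mentions through a timing-window rule,
    rendered as duration-weighted Gaussian heatmaps, and converted to
    grid-cell annotations that drive a multiple-instance-learning loss
    with balanced range normalization plus a multi-task decoder loss.
    Includes a multi-resolution convolutional encoder/decoder with
    hand-derived gradients, a training and IoU/AUC evaluation harness, a
    synthetic reading-session generator for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    pROC,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
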