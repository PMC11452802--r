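Package: ticscreen
Title: Video-Based Tic Summary Scores and Diagnostic Classification for
    Tourette Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical stage of automated video-based tic
    assessment in Gilles de la Tourette syndrome (GTS). Converts per-second
    tic probabilities from an upstream detector into five tic summary scores
    (proportion of tic intervals, mean tic probability, maximal tic and
    tic-free segment durations, and tic clusters per minute), classifies
    videos as GTS versus healthy control with matched-pair leave-pair-out
    cross-validated logistic regression (balanced accuracy, ROC/AUROC), and
    evaluates a hybrid human/machine decision scheme in which low-confidence
    automated predictions are routed to expert review. Includes a synthetic
    cohort generator producing matched GTS/control pairs of per-second tic
    probability series with temporally clustered tic events, so the whole
    pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
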