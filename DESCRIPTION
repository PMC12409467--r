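Package: cmmaturity
Title: Video-Based Maturity Assessment of iPSC-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive maturity assessment of human induced pluripotent
    stem cell-derived cardiomyocytes (iPSC-CMs) from video recordings of
    spontaneous beating. Implements exhaustive block-matching motion
    estimation to recover tissue motion-speed traces, automated beating-cycle
    segmentation and extraction of ten contractility features, a balanced and
    stratified support-vector-machine study design with random and grid
    hyperparameter search, hyperplane-distance maturity scoring, and exact
    Shapley-value feature attribution by full coalition enumeration. A
    synthetic-data module generates beating traces, ground-truth videos and
    labelled feature tables so the whole pipeline is testable without
    microscope recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
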