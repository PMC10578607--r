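Package: exemplaRT
Title: Reaction-Time-Guided Exemplar Curation and Network-Confidence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying whether small training sets curated from human
    reaction times can train image classifiers efficiently. Provides a synthetic
    glyph-stimulus generator with graded typicality, a two-boundary drift-diffusion
    simulator of participants, rank-based scoring of exemplar difficulty from
    reaction times, good/bad/random training-set curation with shift-and-rotation
    augmentation, a small convolutional network classifier with ensemble training
    and softmax-entropy confidence, EZ-style drift-rate estimation, and Spearman
    correlation analyses relating network confidence to reaction times and fitted
    drift rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
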