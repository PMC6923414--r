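Package: secretr
Title: Two-Stage Prediction of Conventional and Unconventional Protein Secretion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage classifier of protein secretion from amino-acid
    sequence alone. Stage one is a compact convolutional network that scans the
    N-terminal 70 residues and separates signal-peptide-bearing proteins,
    proteins with an N-terminal transmembrane domain, and proteins with neither
    signal. Stage two classifies the remaining proteins as unconventionally
    secreted or intracellular from eight physicochemical sequence features
    selected out of a 61-feature description (amino-acid composition, molecular
    weight, and grouped-residue frequencies over sequence segments). The package
    ships the full training machinery (nested cross-validation, minority-class
    oversampling, importance- and drift-based feature selection, probability
    calibration, Matthews-correlation metrics) and a seeded synthetic-sequence
    generator so the whole system can be trained and evaluated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
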