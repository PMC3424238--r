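Package: epifuse
Title: Sequence-Based Conformational B-Cell Epitope Prediction by
    Ensemble Score Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conformational B-cell epitope residues from antigen
    primary sequence alone.  Each residue is represented by a sliding
    window encoded under up to nine feature schemes (physicochemical
    propensities, sparse one-hot profile, amino acid composition,
    function-group one-hot, functional composition, evolutionary PSSM
    profile, amino acid pair profile, predicted secondary structure and
    predicted relative accessible surface area).  Class imbalance is
    handled by training a bootstrap ensemble of random forests per
    encoding on rebalanced samples, and the per-encoding sub-classifier
    scores are fused by a weighted sum after tanh-estimator
    normalization, with weights found by exhaustive simplex grid search.
    Includes antigen-level leave-one-out cross-validation, a synthetic
    antigen generator with plantable epitope signal, readers and writers
    for FASTA, PSI-BLAST ASCII PSSM and per-residue annotation tables,
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
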