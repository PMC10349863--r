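Package: mutsigdyn
Title: Mutational Signature Dynamics Across Cancer Disease Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how somatic mutational processes change during
    cancer evolution, modelled on the progression of oesophageal
    adenocarcinoma from Barrett Oesophagus through primary tumours to
    metastasis. The package refits SBS-96 and ID-83 mutational signature
    exposures by constrained regression with small-contribution pruning,
    decomposes mutations into clonal-early, clonal-late and subclonal
    compartments from allele frequencies, purity and allele-specific copy
    number, measures nucleosome-relative mutation-rate periodicity with a
    pentamer-preserving randomization null and an oversampled periodogram,
    scores DNA-damage-repair pathway alterations and chromosomal
    instability, calls repair-deficiency phenotypes, compares signature
    dynamics across disease stages, and classifies disease stage from
    signature features. A fully synthetic cohort generator with known
    ground truth (genome, nucleosome dyads, variants, copy-number
    profiles, clinical table) supports end-to-end parameter-recovery
    testing without access to restricted patient data.
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
    glmnet,
    jsonlite,
    pracma,
    pROC,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
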