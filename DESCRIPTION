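Package: lectinpred
Title: Multiview Sequence Features and Two-Step Selection for Cancerlectin Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A protein-sequence classification toolkit for predicting
    cancer-associated lectins (cancerlectins). Encodes sequences with four
    complementary feature views -- composition/transition/distribution (CTD,
    147 features), classical pseudo amino acid composition (PseAAC, 70),
    PSSM-derived evolutionary features (PSSM-AAC plus PsePSSM autocovariance,
    120), and intrinsic-disorder summaries (28) -- balances classes with
    SMOTE, selects features by a two-step ReliefF filter plus sequential
    forward selection wrapper, and evaluates Random-Forest classifiers under
    stratified 5-fold cross-validation with Sn/Sp/Acc/MCC and ROC/AUC. A
    synthetic-data generator emits labelled FASTA, PSI-BLAST ASCII PSSM and
    per-residue disorder fixtures so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    class,
    e1071,
    rpart,
    pROC,
    withr
Config/testthat/edition: 3
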