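Package: breakclock
Title: Aging Clocks from Genome-Wide Maps of DNA Single-Strand Breaks and
    Abasic Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns nucleotide-resolution genome-wide maps of single-strand
    DNA breaks (SSBs) and abasic (AP) sites into per-gene lesion densities
    (LPKM, lesions per kb per million), ranks genes by a one-way ANOVA
    F-score for association with age group or tissue, and builds and
    evaluates age and tissue prediction models under a repeated random
    train/test split protocol with one-vs-rest macro AUC, macro F1, MAE and
    Spearman correlation. Includes gene-level TPM from read counts for
    transcriptome comparison, Spearman age screens with per-tissue
    correlation-range analysis, hypergeometric gene-set overlap tests, and a
    synthetic breakome generator with a ground-truth manifest so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    methods,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
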