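Package: cgimeth
Title: Feature-Based Prediction of CpG Island Methylation Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for predicting the DNA methylation status of CpG
    islands from genomic and epigenomic features. Converts per-CpG or
    per-probe methylation measurements into binary island labels, computes
    a 948-dimensional feature vector across 15 feature classes (sequence
    composition, periodic CpG spacing, annotation context, position
    frequency matrix motif scores, DNA structure energies, conservation
    and histone modification signal), and trains and evaluates binary
    classifiers and support vector regression models with repeated
    stratified cross-validation, MCC-centric scoring, RBF grid search and
    per-mille prediction certainty scores. Includes a synthetic fixture
    generator so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071,
    randomForest,
    rpart,
    class,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
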