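Package: ProtamineScan
Title: Protamine Prediction from Protein Sequences via Pseudo Amino Acid
    Composition and Augmented Machine Learning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies protamines (small arginine-rich sperm nuclear
    proteins) from primary amino acid sequence. Sequences are featurized
    as 30-dimensional type-I pseudo amino acid composition vectors
    (20 residue frequencies plus lambda = 10 sequence-order correlation
    factors built from hydrophobicity, hydrophilicity and side-chain
    mass scales). Class imbalance is addressed either by SMOTE
    interpolation or by a tabular generative adversarial network trained
    on the minority class. Eight classifier families are benchmarked
    under stratified 10-fold cross-validation plus an independent 80/20
    split, with accuracy, sensitivity, precision, F1, Cohen's kappa,
    Matthews correlation and ROC AUC reported. A synthetic benchmark
    generator emulating arginine-dominated protamine-like sequences
    makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    optparse,
    randomForest,
    xgboost,
    e1071,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Proteomics, MachineLearning, SupportVectorMachine,
    FeatureExtraction
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'ProtamineScan-package.R'
    'seqio.R'
    'pseaac.R'
    'augment.R'
    'metrics.R'
    'modeling.R'
    'cli.R'
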