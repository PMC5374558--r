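Package: phagehost
Title: Alignment-Free Prediction of Phage-Host Infectious Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts whether a viral genome or contig infects a given
    bacterial host genus from k-mer word frequencies, optionally normalized
    against per-sequence Markov-chain background models (the F1-F4 feature
    family). Implements the cutting-year evaluation protocol with repeated
    negative resampling and rank AUC, Manhattan and d2*-type dissimilarity
    baselines, a contig fragmentation and sequencing-error simulator with a
    cross-length training/testing grid, a beta-mixture maximum-likelihood
    estimator of the fraction of truly infectious viruses in viral-tagging
    score sets, and a seeded synthetic benchmark generator built on
    host-specific Markov models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    e1071,
    glmnet,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
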