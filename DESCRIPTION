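Package: selfgp
Title: Semi-Supervised Self-Training for Genomic Prediction of Feed Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of novel, expensive-to-measure traits
    such as residual feed intake (RFI) in dairy cattle when the reference
    population is small. Implements a self-training (semi-supervised) wrapper
    around an RBF-kernel support-vector regression base predictor, derivation
    of per-animal RFI phenotypes from weekly dry-matter-intake records via a
    REML-fitted linear mixed model with random ration-cohort effects, SNP
    quality control (minor-allele orientation, MAF filtering, rounded-frequency
    imputation), a quantitative-genetics simulator for end-to-end testing, and
    the validation designs used to study self-training: supervised learning
    curves, labeled/unlabeled ratio sweeps, and plateau searches for the
    optimal number of self-trained animals, with replicate summaries and 95%
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
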