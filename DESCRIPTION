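Package: prsauc
Title: Predict Polygenic Risk Score AUC from Training GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the out-of-sample area under the ROC curve (AUC) of a
    case-control polygenic risk score (PRS) using only the GWAS summary
    statistics that trained it, so that PRS hyperparameters can be tuned
    without an external validation cohort. Observed allele-frequency
    differences are shrunk with an empirical-Bayes point-normal prior:
    an expectation-maximization fit with a closed-form posterior when the
    pre-selected SNPs are independent, and a State-Augmentation for
    Marginal Estimation (SAME) Gibbs sampler when SNPs are linked by
    linkage disequilibrium (LD). Includes block-wise Ledoit-Wolf LD
    estimation from a reference genotype panel, PLINK bed/bim/fam input,
    minimal pruning/clumping/thresholding and spike-and-slab weight
    generators, and a simulation framework with independent and AR(1)
    genotype architectures for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
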