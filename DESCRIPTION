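Package: reactnorm
Title: Reaction-Norm GWAS for General Production and Environmental
    Sensitivity in Progeny-Test Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps genetic variation in general production (reaction-norm
    intercept) and environmental sensitivity (reaction-norm slope) of
    quantitative traits recorded on half-sib daughter groups, as in dairy
    progeny-test designs.  Provides a random-regression sire-model REML/BLUP
    fit with correlated intercept/slope effects and decile-heterogeneous
    residual variances, a kinship-controlled single-SNP mixed-model
    association scan with Storey q-values and a discovery/validation
    replication protocol, a log-transform decomposition separating scaling
    from non-scaling genotype-by-environment interaction, pedigree numerator
    relationship matrices, PLINK text genotype I/O with the usual marker and
    individual quality-control filters, and a fully parameterised synthetic
    progeny-test data generator with retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
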