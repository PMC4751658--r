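Package: genoclass
Title: Genomic Prediction of Unordered Categorical Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multinomial genomic prediction for unordered categorical traits
    (such as breed or subpopulation assignment) built from binary Bayesian
    probit threshold models on SNP covariates. Binary contrasts are fitted by
    data-augmentation Gibbs sampling under ridge (GBLUP), BayesA or BayesC-pi
    marker-effect priors and combined into multinomial classifiers by
    one-vs-all normalization, one-vs-one voting, or one-vs-one pairwise
    probability coupling. Includes leave-one-out cross-validation with
    accuracy, Brier score and scaled Brier score; VanRaden genomic and
    pedigree numerator relationship matrices; population-divergence
    statistics (pairwise and global F_ST, eigenvector-inclusion analysis,
    liability-scale heritability of subpopulation assignment); multinomial
    breeding values; and a Balding-Nichols synthetic-population simulator
    with admixture and half-sib family structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    vcfR,
    e1071,
    lme4,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr
Config/testthat/edition: 3
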