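Package: genobin
Title: Genome-Bin Infinitesimal Models for Quantitative Trait Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses dense marker panels into genome-bin covariates for
    whole-genome prediction of quantitative traits. Bins are contiguous
    genome intervals whose markers are collapsed into one covariate: an
    unweighted genotype average for high linkage-disequilibrium populations
    (line crosses), or an adaptively weighted score -- with signed weights
    derived from single-marker least-squares estimates -- for low-LD
    populations. Bin effects are fitted by L1-penalized regression and
    tested with approximate Wald/LOD statistics; predictive ability is
    quantified by k-fold cross-validation mean squared error and R-squared,
    with a scan over bin sizes to locate the optimum. Includes an F2
    cross simulator (Haldane map function) with oligogenic, clustered
    polygenic, uniform polygenic and no-LD trait architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
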