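Package: causalmix
Title: Bivariate Causal Mixture Models for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates polygenic overlap between two complex traits from GWAS
    summary statistics and a linkage-disequilibrium (LD) reference, using a
    four-component bivariate Gaussian mixture prior on per-variant causal
    effects. Provides sparse LD estimation with heterozygosity-adjusted LD
    scores, harmonization of summary statistics, fast (method-of-moments) and
    full (sampled causal configurations) z-score likelihoods, staged
    Nelder-Mead maximum likelihood with information criteria, Fisher-information
    standard errors with sampling-based error propagation, and derived
    quantities: SNP heritability, genetic correlation, causal-variant Venn
    counts, GWAS power curves and model-predicted quantile-quantile plots. A
    synthetic-data stack (block-LD panels, MAF-dependent architectures,
    z-score and genotype-level GWAS simulation) makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    mvtnorm,
    numDeriv,
    purrr,
    readr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
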