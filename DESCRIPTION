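Package: rrgwas
Title: Two-Step Longitudinal GWAS for Repeated-Parity Traits via Random
    Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal genome-wide association analysis of
    traits recorded repeatedly over parities, such as dairy-cow fertility
    traits. Implements a two-step strategy: restricted maximum likelihood
    (average-information REML) estimation of intercept and slope
    (co)variance components on a first-order Legendre basis in a random
    regression model with pedigree, genomic or combined (single-step H)
    relationship matrices and an optional service-sire effect, followed by
    per-SNP generalized least squares Wald tests of intercept, slope and
    joint effects with an eigen-decomposition fast path. Includes genotype
    quality control, VanRaden genomic relationships, PCA/k-means
    stratification checks, genomic-inflation and threshold summaries,
    candidate-gene windowing against GFF3/BED annotation, layered Manhattan
    and Q-Q plots, and a synthetic-data generator (pedigree gene dropping,
    multi-parity phenotypes with declining record counts) so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr,
    yaml
Suggests:
    GenomicRanges,
    lme4,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
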