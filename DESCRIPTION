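Package: transqtl
Title: Trans-eQTL Discovery, Colocalization and Cis-Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide trans-eQTL discovery and
    interpretation in genotype-expression cohorts. Implements GTEx-style
    expression normalization (quantile plus rank-based inverse normal
    transform), hidden-factor and genotype-PC covariate construction,
    matrix-accelerated cis/trans association scanning with cross-mappability
    filtering and greedy LD pruning, three multiple-testing schemes (pooled
    Benjamini-Hochberg, hierarchical gene-level Sidak, and permutation-based
    gene-level FDR), approximate-Bayes-factor colocalization of association
    traces, quasi-Bayesian causal mediation of SNP effects through cis genes,
    trans-eQTL hotspot detection with expression-matched resampling nulls,
    interchromosomal Hi-C contact enrichment, and GWAS locus clumping with
    risk-gene colocalization. Ships a synthetic-cohort generator with planted
    regulatory architecture and full ground-truth export for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    limma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
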