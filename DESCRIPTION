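Package: pathgwas
Title: Pathway-Level Analysis of Case-Control GWAS Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pathway- and gene-level association analysis for case-control
    genome-wide association studies. Implements SNP-level quality control
    (call rate, minor allele frequency, exact Hardy-Weinberg test, gene-desert
    exclusion), genomic inflation diagnostics (lambda and lambda-1000),
    EIGENSTRAT-style principal components for population structure, per-gene
    eigenSNP compression, the GRASS pathway test (ridge-penalized logistic
    regression on pathway eigenSNPs with permutation-standardized gene
    statistics and a two-stage permutation p-value), the logistic kernel
    machine score test per gene with Davies/Imhof p-values, Stouffer z-score
    meta-analysis across cohorts, and DAVID-style functional enrichment
    scoring (EASE p-values, kappa clustering, cluster enrichment scores).
    Ships a synthetic case-control genotype generator with gene-level linkage
    disequilibrium, pathway-embedded causal effects, covariates, and optional
    population structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
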