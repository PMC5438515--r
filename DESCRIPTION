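Package: survscan
Title: Genome-Wide Survival Association Scans for Imputed Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-variant association scanning of genome-wide genotype data
    against time-to-event outcomes, aimed at pharmacogenetic studies where
    the endpoint is death, remission or an adverse drug reaction. Reads
    Oxford GEN/sample files (plain, gzip or zip) and VCF files carrying
    genotype probabilities, dosages or hard calls; converts genotype
    probabilities to additive allele dosages with allele-frequency and
    IMPUTE-info imputation-quality annotation; and fits a Cox proportional
    hazards or parametric Weibull regression model per variant, with
    covariates and SNP-covariate interactions, reporting Wald, score and
    likelihood-ratio tests. Scans stream the genotype file in line-range
    batches so memory use is independent of the number of variants.
    Includes a synthetic-data generator for proportional-hazards and
    accelerated-failure-time outcomes with imputation-like genotype
    uncertainty, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
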