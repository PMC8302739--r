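Package: ctprs
Title: Clumping-and-Thresholding Polygenic Risk Scores with APOE-Aware
    Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates Alzheimer's disease polygenic risk scores
    by the clumping + thresholding (C+T) method. Provides summary-statistic
    and genotype input with allele harmonisation, greedy LD clumping and
    p-value thresholding, weighted-sum scoring with mean imputation, APOE
    isoform coding from rs429358/rs7412 and the named APOE-aware score
    models, principal-component adjustment with in-sample and
    population-referenced standardisation, extreme-tail classification with
    Haldane-corrected odds ratios and AUC, and a seeded case-control cohort
    simulator with hidden (not-yet-onset) cases among the controls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'apoe.R'
    'clump.R'
    'ctprs-package.R'
    'evaluate.R'
    'filters.R'
    'harmonize.R'
    'pipeline.R'
    'read-io.R'
    'score.R'
    'simulate.R'
    'standardize.R'
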