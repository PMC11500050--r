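Package: kcmeta
Title: Two-Cohort GWAS Meta-Analysis, Polygenic Scoring, and Gene
    Prioritization for Keratoconus-Style Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a two-cohort case-control GWAS
    workflow for complex ocular disease: per-SNP logistic association with
    principal-component adjustment and quality control, inverse-variance
    fixed-effects meta-analysis with Cochran's Q and I-squared heterogeneity
    and gray-zone signal classification, LD-based definition of independent
    significant SNPs, lead SNPs and merged genomic risk loci, clumping-and-
    thresholding polygenic risk scores with Nagelkerke delta-R2 grid search
    and label-permutation calibration, a tier-based variant-to-gene evidence
    ledger (pLI, CADD, ncRVIS, RegulomeDB, eQTL, chromatin interaction), a
    protein-interaction edge-count enrichment test, and a drug-target
    repositioning join. Includes a synthetic-data generator with LD-blocked
    genotypes and additive logistic disease risk so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pROC,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
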