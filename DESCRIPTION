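Package: ctdnasig
Title: Tumor Expression Classifiers of ctDNA Detectability in Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates gene-expression classifiers of circulating
    tumor DNA (ctDNA) detectability from multi-cohort breast tumor microarray
    data. Provides a synthetic multi-cohort study generator with planted
    differential probes, batch effects and recurrence-free survival; simplified
    RMA-style per-cohort normalization (quantile normalization and median-polish
    summarization); meta-analytic probe ranking (Hedges g combined by
    DerSimonian-Laird random effects); sequential forward feature selection of a
    linear support-vector machine assessed by leave-one-out cross-validation;
    diagnostic metrics, association tests and odds ratios for 2x2 tables;
    Kaplan-Meier and log-rank survival comparison; hypergeometric (and EASE)
    gene-set over-representation against GMT annotations; and digital-PCR
    mutant-allele-fraction calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
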