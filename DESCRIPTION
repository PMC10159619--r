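Package: PRSeval
Title: Polygenic Risk Score Evaluation in Prospective Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores published polygenic-score weight files (PGS Catalog
    format) on cohort genotype dosages, with allele harmonization and
    variant-level quality control, and evaluates each score's distribution,
    discrimination (Mann-Whitney AUC with DeLong intervals and a 5-year
    cumulative/dynamic AUC), hazard-ratio stratification by PRS quantile
    with the middle quintile as reference, 5-year absolute risk under
    competing mortality via an iterative constrained baseline-hazard
    solver, and calibration (decile expected-versus-observed slope and
    Hosmer-Lemeshow test).  Includes a synthetic prospective-cohort
    generator (Hardy-Weinberg genotypes, proportional-hazards outcomes,
    competing death, administrative censoring) so the full pipeline is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    data.table,
    stats,
    utils,
    survival,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
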