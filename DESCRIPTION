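Package: ddx
Title: Differential Genetic Association Between Two Disorders from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates SNP-level genetic differences between two disorders
    directly from their genome-wide association study (GWAS) summary
    statistics, treating one disorder as "case" and the other as
    "pseudo-control". Implements harmonization of summary-statistics pairs,
    the differential (case-case) association test with sample-overlap
    correction via the cross-trait LD-score-regression intercept, genomic
    control, a minimal LD-score regression for SNP heritability and
    cross-trait intercepts with block-jackknife errors, liability-threshold
    prediction metrics (maximum polygenic-score AUC, absolute risk by score
    percentile, relative-risk tables, ROC and predictiveness curves),
    empirical-Bayes (Tweedie) forecasting of polygenic-score discrimination
    across p-value thresholds, and a case-control genotype simulator with
    overlapping controls and comorbidity for validating the differential
    estimator against a direct case-versus-case GWAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
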