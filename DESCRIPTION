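Package: bpmr
Title: Two-Sample Mendelian Randomization of Blood Pressure on Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of genetically
    predicted blood pressure on atrial fibrillation risk. Reads and validates
    GWAS summary statistics, harmonizes exposure and outcome effect alleles,
    performs greedy LD clumping, and estimates causal effects with
    inverse-variance weighted (multiplicative random effects), weighted-median
    and MR-Egger models reported as odds ratios per 10 mm Hg. Includes
    per-variant instrument-strength metrics (R-squared and F), an analytic
    approximation of bias from exposure-outcome sample overlap, drug-target
    proxy instruments (target-gene regions and validated eQTLs) for
    antihypertensive drug classes, and a synthetic summary-statistics
    generator for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
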