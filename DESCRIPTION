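Package: phewasmr
Title: Phenome-Wide Mendelian Randomization with Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for phenome-wide Mendelian randomization
    (MR) of a binary exposure against many ICD-derived disease outcomes.
    Includes a liability-threshold cohort simulator with linkage
    disequilibrium blocks and palindromic variants, phecode construction
    from ICD-9/ICD-10 diagnosis records, split-sample GWAS, LD clumping and
    polygenic risk scoring, a PheWAS logistic scan with Bonferroni control,
    one-sample (two-stage) MR, and a two-sample MR suite with the standard
    sensitivity battery: MR-Egger, weighted median and mode, Cochran's Q,
    MR-PRESSO global/outlier/distortion tests, Steiger directionality,
    leave-one-out, and pleiotropy pruning. Log-odds estimates can be scaled
    to per-doubling odds ratios, and analytic MR power for binary outcomes
    is provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
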