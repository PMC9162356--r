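Package: curmr
Title: Mediation-Corrected Instrument Selection for Mendelian Randomization of Dietary Intake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for causal inference on diet-health relationships from GWAS
    summary statistics. Corrects per-variant SNP effects on reported food intake
    for components mediated through other traits (multivariable Mendelian
    randomization priors), classifies variants by the corrected-to-uncorrected
    ratio (CUR), builds principal-component dietary-pattern traits from a
    genetic-correlation matrix, and runs CUR-filtered two-sample Mendelian
    randomization with heterogeneity, pleiotropy and outlier diagnostics.
    Includes a synthetic-data generator for individual-level cohorts and
    summary statistics under a linear structural equation model with
    bidirectional causal effects, confounding and questionnaire
    measurement noise, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
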