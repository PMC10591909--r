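Package: egrsyn
Title: Drug Synergy Assessment for Four-Group In Vivo Combination Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses drug synergy in single-dose, four-group (control, A, B,
    A+B) mouse combination studies from longitudinal tumor-volume data. Each
    growth curve is summarized by an exponential growth rate (eGR) derived
    from the net log-scale area under the curve, groups are compared through
    relative survival fractions, and combination indices and synergy scores
    are computed under the Bliss independence and highest-single-agent
    models with stratified bias-corrected and accelerated (BCa) bootstrap
    confidence intervals and P values. Includes an exponential tumor-growth
    simulator (treatment effect, delayed kick-in, intrinsic and induced
    resistance, animal-to-animal variation, measurement noise, euthanasia
    truncation) and an empirical power-analysis framework for study design,
    plus a single-day log-ratio Bliss index baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
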