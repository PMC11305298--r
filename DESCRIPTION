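Package: psopd
Title: Pharmacodynamic Biomarker Analysis for Psoriasis Treatment Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pharmacodynamic biomarker responses in
    psoriasis clinical studies with paired lesional/nonlesional skin
    biopsies and longitudinal serum sampling. Derives a psoriatic skin
    transcriptomic signature from paired baseline differential expression,
    quantifies treatment effect per gene as a percent-improvement
    (normalization) statistic, identifies a residual molecular scar in
    healed skin of complete responders, performs hypergeometric gene-set
    enrichment and sample-level gene set variation scoring, computes serum
    cytokine case-control and longitudinal contrasts (Welch tests, paired
    tests, baseline-adjusted ANCOVA), and derives capped signed fold
    changes from qPCR delta-Ct data. Includes a synthetic cohort generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    emmeans,
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
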