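Package: uromarker
Title: Urinary Biomarker Panels for Discriminating UTI from Asymptomatic
    Bacteriuria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for evaluating infection-associated urinary
    biomarkers (NGAL, IL-8, IL-1beta) as a diagnostic aid for urinary tract
    infection in older adults. Implements dual-modality (multiplex PCR and
    standard urine culture) case definitions for definitive UTI versus
    definitive non-UTI, fixed-cutoff and consensus (2-of-3) biomarker
    classification, diagnostic performance with Clopper-Pearson exact
    confidence intervals and likelihood ratios, probit dose-response of
    biomarker positivity against log microbial density, and a seeded
    synthetic cohort generator reproducing the statistical structure of a
    two-cohort (symptomatic urology / asymptomatic community) study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
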