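Package: twindff
Title: Calcium Response Quantification and Random-Effects Twin Contrasts
    for Discordant-Twin iPSC Studies
Version: 0.1.0
Authors@R:
    person(given = "Package", family = "Author",
           email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing stimulus-evoked calcium-imaging responses of
    iPSC-derived neurons from monozygotic twin pairs discordant for disease.
    Implements baseline-normalised response quantification (dF* = (f - f0)/f0)
    on stationary-wavelet-denoised ROI fluorescence traces with ionomycin and
    KCl calibration, robust MAD outlier filtering, a two-level random-effects
    twin-contrast test with a DerSimonian-Laird between-pair variance
    estimator, and gene-set overlap enrichment statistics for sex-specific
    differential-expression analyses. Ships a synthetic-data generator that
    produces twin cohorts of fluorescence recordings and differential
    expression tables with known ground truth, so the whole pipeline is
    testable end to end without any raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
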