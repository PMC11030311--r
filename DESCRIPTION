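Package: rmcr
Title: Regional Missense Constraint and Variant Deleteriousness from Population Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects sub-genic regions of missense depletion (missense
    constraint regions, MCRs) by a recursive Poisson likelihood-ratio
    segmentation of transcripts against a calibrated neutral mutational
    expectation. Includes the mutational null model (plateau calibration of
    trinucleotide-context mutation rates and low-coverage correction), the
    MPC missense deleteriousness score built on regional constraint via a
    logistic model and a rank-based transform, calibration of score
    thresholds to ACMG/AMP clinical evidence strengths from labeled
    variants, case/control enrichment statistics (rate ratios and
    top-percentile odds ratios), and a synthetic-data generator that
    produces every input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    magrittr,
    jsonlite,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
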