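Package: coumascreen
Title: Outlier-Based Discovery of VKORC1 Variants Affecting Coumarin Dose
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for screening anticoagulated cohorts for
    patients whose stable acenocoumarol dose escapes the reference range of
    their combined VKORC1/CYP2C9 genetic profile, and for characterising the
    rare VKORC1 variants enriched among those outliers. Implements
    genotype-profile reference dosing, per-profile mean +/- 2SD outlier
    flagging with a clinical exclusion cascade, two-locus EM haplotype
    frequency estimation with D'/r-squared linkage disequilibrium statistics
    and detection of individuals discordant with the dominant haplotype pair,
    carrier association t tests, and forward stepwise additive regression of
    weekly dose reporting the cumulative R-squared ladder. A calibrated
    synthetic-cohort generator reproduces the genotype frequencies, LD
    structure, rare-variant carrier rates and additive dose model of a large
    published acenocoumarol cohort so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
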