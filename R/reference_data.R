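#' Published reference tables for the acenocoumarol outlier study
#'
#' The generator and the worked examples are calibrated against the summary
#' tables of a large published cohort of 3949 acenocoumarol-treated Caucasian
#' patients. These functions return those printed numbers as data frames so
#' that every calibration constant in [default_cohort_config()] is traceable
#' to a published count rather than a magic number.
#'
#' @return `published_profile_table()`: one row per genetic profile (CYP2C9
#'   diplotype crossed with VKORC1 rs9923231 genotype) with cohort count,
#'   reference weekly dose mean and SD (mg/week), and outlier counts.
#' @examples
#' published_profile_table()
#' @export
published_profile_table <- function() {
  tab <- data.frame(
    profile_id = 1:18,
    cyp2c9   = rep(c("*1*1", "*1*2", "*1*3", "*2*2", "*2*3", "*3*3"), each = 3),
    vkorc1   = rep(c("GG", "GA", "AA"), times = 6),
    n        = c(782, 1132, 390, 349, 486, 156, 160, 216, 66,
                 37, 56, 18, 35, 44, 12, 4, 5, 1),
    dose_mean = c(18, 14, 9, 17, 13, 9, 14, 10, 7,
                  15, 11, 8, 13, 9, 5, 5, 11, 6),
    dose_sd   = c(7, 5, 4, 6, 5, 3, 5, 4, 3,
                  4, 6, 3, 5, 3, 1, 2, 10, NA),
    n_outlier       = c(13, 11, 8, 6, 9, 0, 4, 2, 3, 0, 1, 0, 0, 0, 0, 0, 0, 0),
    n_outlier_below = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  tab$n_outlier_above <- tab$n_outlier - tab$n_outlier_below
  tab
}

#' @rdname published_profile_table
#' @return `published_variant_table()`: per rare/low-frequency VKORC1 variant,
#'   whole-sample genotype counts (non-carrier, heterozygote, homozygote) and
#'   the carrier / non-carrier dose summaries (mg/week). `NA` where the study
#'   could not genotype the whole sample (L128R).
#' @export
published_variant_table <- function() {
  data.frame(
    variant_id = c("D36Y", "L128R", "rs55894764", "rs7200749", "rs17878544"),
    n_ref = c(3935, NA, 3744, 3861, 3782),
    n_het = c(14,   NA, 198,  85,   161),
    n_hom = c(0,    NA, 4,    3,    5),
    dose_mean_noncarrier = c(14, NA, 14, 14, 14),
    dose_sd_noncarrier   = c(6,  NA, 5,  6,  6),
    dose_mean_carrier    = c(22, NA, 16, 16, 15),
    dose_sd_carrier      = c(9,  NA, 6,  7,  7),
    p_printed = c(0.004, NA, 0.001, 0.001, 0.002),
    stringsAsFactors = FALSE
  )
}

#' @rdname published_profile_table
#' @return `published_discordant_patients()`: the six whole-sample patients
#'   whose rs9923231/rs9934438 two-locus genotypes cannot be composed from the
#'   two dominant haplotypes (G-C and A-T).
#' @export
published_discordant_patients <- function() {
  data.frame(
    patient = LETTERS[1:6],
    age = c(65, 70, 82, 78, 48, 65),
    sex = c("female", "female", "female", "female", "male", "female"),
    rs9923231 = c("GG", "GA", "GA", "GA", "AA", "AA"),
    rs9934438 = c("CT", "CC", "TT", "TT", "CT", "CT"),
    cyp2c9 = c("*1*1", "*1*2", "*1*1", "*1*1", "*1*1", "*1*2"),
    weekly_dose = c(19, 18, 5, 9, 24, 12),
    stringsAsFactors = FALSE
  )
}

#' @rdname published_profile_table
#' @return `published_stepwise_ladder()`: the published stepwise regression
#'   summary — entry order, cumulative R-squared after each entry, and the
#'   standardized coefficient of each predictor in the final model.
#' @export
published_stepwise_ladder <- function() {
  data.frame(
    predictor = c("rs9923231", "age", "cyp2c9", "D36Y", "rs55894764"),
    cumulative_r2 = c(0.210, 0.340, 0.391, 0.395, 0.400),
    beta_standardized = c(-0.461, -0.364, -0.216, 0.061, 0.034),
    beta_p = c(0.001, 0.001, 0.001, 0.001, 0.006),
    stringsAsFactors = FALSE
  )
}

#' @rdname published_profile_table
#' @return `published_exclusion_counts()`: named integer vector; among the 145
#'   flagged patients, how many were excluded per clinical category (plus
#'   missing clinical data), in the canonical attribution order used by
#'   [apply_exclusions()].
#' @export
published_exclusion_counts <- function() {
  c(autoimmune_disease = 10L,
    liver_failure = 6L,
    severe_heart_failure = 8L,
    severe_copd = 10L,
    interacting_drugs = 37L,
    new_thrombotic_event = 6L,
    obesity = 2L,
    tumoral_disease = 5L,
    no_clinical_data = 4L)
}
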