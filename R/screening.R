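#' Flag patients whose dose lies outside their profile's mean +/- 2SD
#'
#' A patient is flagged when `|dose - mean| > 2 * SD` strictly, using the
#' reference statistics of their genetic profile ("outside" treats a dose on
#' the boundary as inside). Patients in profiles not usable for screening
#' (too few patients for a stable SD) are never flagged; they are counted and
#' reported via a message.
#'
#' @param cohort Cohort data frame.
#' @param reference_table Output of [reference_dose_table()]; defaults to the
#'   table computed from `cohort` itself (the one-pass design: reference
#'   statistics include the prospective outliers).
#' @return Data frame of outlier calls: `patient_id`, `profile_id`,
#'   `flagged`, `direction` ("above"/"below"/"none"), `screened`.
#' @export
flag_outliers <- function(cohort, reference_table = reference_dose_table(cohort)) {
  pid <- assign_profile(cohort$rs9923231, cohort$rs1799853, cohort$rs1057910)
  ref <- reference_table[match(pid, reference_table$profile_id), ]
  screened <- !is.na(pid) & ref$screened
  dev <- cohort$weekly_dose - ref$mean_dose
  flagged <- screened & abs(dev) > 2 * ref$sd_dose
  direction <- rep("none", nrow(cohort))
  direction[flagged & dev > 0] <- "above"
  direction[flagged & dev < 0] <- "below"
  n_skip <- sum(!screened)
  if (n_skip > 0) {
    message("flag_outliers: ", n_skip,
            " patient(s) in unscreened profiles (small n or missing genotype)")
  }
  data.frame(patient_id = cohort$patient_id, profile_id = pid,
             flagged = flagged, direction = direction, screened = screened,
             stringsAsFactors = FALSE)
}

#' Apply the clinical exclusion cascade to flagged outliers
#'
#' Flagged patients carrying any clinical-condition flag (or the
#' no-clinical-data marker) are excluded; the rest are retained as true
#' outliers. A patient with several flags is excluded once, attributed to the
#' first matching category in the canonical [clinical_flag_levels()] order,
#' so the per-category tallies are disjoint and sum to the number excluded.
#'
#' @param calls Output of [flag_outliers()].
#' @param cohort The cohort the calls were computed on.
#' @return List with `calls` (input plus `retained` and `exclusion_reason`
#'   columns), `tally` (named integer vector per category), `n_flagged`,
#'   `n_excluded`, `n_retained`.
#' @export
apply_exclusions <- function(calls, cohort) {
  stopifnot(identical(calls$patient_id, cohort$patient_id))
  flags <- parse_clinical_flags(cohort$clinical_flags)
  levels <- clinical_flag_levels()
  first_reason <- vapply(flags, function(f) {
    hit <- levels[levels %in% f]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  calls$exclusion_reason <- ifelse(calls$flagged, first_reason, NA_character_)
  calls$retained <- calls$flagged & is.na(calls$exclusion_reason)
  excluded <- calls$flagged & !is.na(calls$exclusion_reason)
  tally <- table(factor(calls$exclusion_reason[excluded], levels = levels))
  tally <- stats::setNames(as.integer(tally), levels)
  res <- list(calls = calls, tally = tally,
              n_flagged = sum(calls$flagged),
              n_excluded = sum(excluded),
              n_retained = sum(calls$retained))
  message("apply_exclusions: ", res$n_flagged, " flagged = ",
          res$n_retained, " retained + ", res$n_excluded, " excluded")
  res
}

#' Exclusion arithmetic on published-style tallies
#'
#' Conservation helper used in reports: flagged = retained + excluded.
#'
#' @param n_flagged Number of flagged patients.
#' @param exclusion_counts Named or unnamed integer vector of disjoint
#'   per-category exclusion counts.
#' @return Number of retained outlier patients.
#' @examples
#' retained_after_exclusions(145, published_exclusion_counts())  # 57
#' @export
retained_after_exclusions <- function(n_flagged, exclusion_counts) {
  if (sum(exclusion_counts) > n_flagged) {
    stop("exclusions exceed flagged count", call. = FALSE)
  }
  as.integer(n_flagged - sum(exclusion_counts))
}
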