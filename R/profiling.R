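#' Assign combined CYP2C9/VKORC1 genetic profiles
#'
#' The 18 profiles are the six CYP2C9 diplotypes (*1*1, *1*2, *1*3, *2*2,
#' *2*3, *3*3) crossed with the three rs9923231 genotypes (GG, GA, AA), in
#' that canonical order: `profile_id = 3 * diplotype_rank + genotype_rank + 1`
#' (ranks counted from 0). So (GG, *1*1) is profile 1, (GA, *1*1) profile 2,
#' ..., (AA, *3*3) profile 18.
#'
#' @param rs9923231 A-allele counts (0/1/2), NA for missing.
#' @param cyp2c9_star2,cyp2c9_star3 Allele counts of CYP2C9 *2 and *3.
#' @return Integer vector of profile ids 1-18; NA where any genotype is
#'   missing (those patients are excluded from profiling, with a message).
#' @examples
#' assign_profile(1, 0, 0)  # (GA, *1*1) -> 2
#' @export
assign_profile <- function(rs9923231, cyp2c9_star2, cyp2c9_star3) {
  n <- length(rs9923231)
  stopifnot(length(cyp2c9_star2) == n, length(cyp2c9_star3) == n)
  known <- !(is.na(rs9923231) | is.na(cyp2c9_star2) | is.na(cyp2c9_star3))
  bad_geno <- known & (!rs9923231 %in% 0:2 | !cyp2c9_star2 %in% 0:2 |
                         !cyp2c9_star3 %in% 0:2)
  if (any(bad_geno)) stop("allele counts must be 0, 1 or 2", call. = FALSE)
  if (any(known & (cyp2c9_star2 + cyp2c9_star3 > 2))) {
    stop("impossible CYP2C9 diplotype: *2 + *3 allele counts exceed 2",
         call. = FALSE)
  }
  # diplotype rank 0..5 for (c2, c3) in {(0,0),(1,0),(0,1),(2,0),(1,1),(0,2)}
  dip_rank <- rep(NA_integer_, n)
  dip_rank[known] <- match(
    paste(cyp2c9_star2[known], cyp2c9_star3[known]),
    c("0 0", "1 0", "0 1", "2 0", "1 1", "0 2")
  ) - 1L
  id <- 3L * dip_rank + as.integer(rs9923231) + 1L
  if (any(!known)) {
    message("assign_profile: ", sum(!known),
            " patient(s) unassignable (missing genotype), excluded")
  }
  id
}

#' Profile id to (CYP2C9 diplotype, VKORC1 genotype) labels
#' @param profile_id Integer vector in 1-18.
#' @return Data frame with `profile_id`, `cyp2c9`, `vkorc1`.
#' @export
profile_labels <- function(profile_id = 1:18) {
  stopifnot(all(profile_id %in% 1:18))
  data.frame(
    profile_id = profile_id,
    cyp2c9 = cyp2c9_diplotypes()[(profile_id - 1L) %/% 3L + 1L],
    vkorc1 = vkorc1_genotypes()[(profile_id - 1L) %% 3L + 1L],
    stringsAsFactors = FALSE
  )
}

#' Per-profile reference dose table
#'
#' For each of the 18 genetic profiles: patient count, sample mean and SD
#' (n - 1 denominator) of the stable weekly dose, and prevalence among fully
#' genotyped patients. Profiles with fewer than `min_n` patients are marked
#' unusable for outlier screening (their SD is too unstable); profiles with
#' n <= 1 have no SD at all.
#'
#' @param cohort Cohort data frame with `weekly_dose`, `rs9923231`,
#'   `rs1799853`, `rs1057910` columns.
#' @param min_n Minimum patients per profile for screening (default 10).
#' @return Data frame with one row per profile (ids 1-18): `profile_id`,
#'   `cyp2c9`, `vkorc1`, `n`, `mean_dose`, `sd_dose`, `prevalence`,
#'   `screened`.
#' @export
reference_dose_table <- function(cohort, min_n = 10) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  pid <- assign_profile(cohort$rs9923231, cohort$rs1799853, cohort$rs1057910)
  assigned <- !is.na(pid)
  tab <- profile_labels()
  tab$n <- as.integer(tabulate(pid[assigned], nbins = 18))
  tab$mean_dose <- vapply(1:18, function(p) {
    d <- cohort$weekly_dose[assigned & pid == p]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  tab$sd_dose <- vapply(1:18, function(p) {
    d <- cohort$weekly_dose[assigned & pid == p]
    if (length(d) > 1) stats::sd(d) else NA_real_
  }, numeric(1))
  tab$prevalence <- tab$n / sum(tab$n)
  tab$screened <- tab$n >= max(min_n, 2) & !is.na(tab$sd_dose)
  tab
}
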