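#' Two-locus haplotype frequencies realizing a target D'
#'
#' Given minor allele frequencies at two loci and a target normalized
#' disequilibrium D' (with positive coupling of the minor alleles), returns
#' the four haplotype frequencies. `D = D' * Dmax` with
#' `Dmax = min(p1 (1 - p2), (1 - p1) p2)`.
#'
#' @param p1,p2 Minor allele frequencies, in (0, 1).
#' @param d_prime Target D' in \[0, 1\].
#' @return Named vector of haplotype frequencies `c(h11, h10, h01, h00)`
#'   where "1" denotes the minor allele.
#' @export
haplotype_freqs_from_ld <- function(p1, p2, d_prime) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, d_prime >= 0, d_prime <= 1)
  d <- d_prime * min(p1 * (1 - p2), (1 - p1) * p2)
  h <- c(h11 = p1 * p2 + d,
         h10 = p1 * (1 - p2) - d,
         h01 = (1 - p1) * p2 - d,
         h00 = (1 - p1) * (1 - p2) + d)
  stopifnot(all(h >= -1e-12))
  pmax(h, 0)
}

draw_haplotype_pair_genotypes <- function(n, freqs, minor1, minor2) {
  idx <- matrix(sample.int(length(freqs), 2 * n, replace = TRUE, prob = freqs),
                nrow = n)
  g1 <- matrix(minor1[idx], nrow = n)
  g2 <- matrix(minor2[idx], nrow = n)
  list(g1 = rowSums(g1), g2 = rowSums(g2))
}

#' Simulate a synthetic anticoagulated cohort
#'
#' Draws genotypes, demographics, clinical-condition flags and stable weekly
#' acenocoumarol doses according to a [cohort_config()]. Genotypes at
#' rs9923231/rs9934438 come from random pairing of the four configured
#' haplotypes (or from marginal genotype frequencies if
#' `vkorc1_genotype_freqs` is set); rs17878544/rs7200749 from a haplotype
#' table realizing the configured D'; CYP2C9 from allele (or diplotype)
#' frequencies; the rare variants as independent carrier Bernoullis. The dose
#' is the additive linear model of the config plus Gaussian noise and a
#' mean-zero uniform shift for patients with a clinical-condition flag,
#' truncated below at 1 mg/week.
#'
#' @param config A validated [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`. Fixed seed gives a
#'   byte-identical cohort.
#' @return A data frame with one row per patient: `patient_id`, `age`, `sex`,
#'   `bmi`, `weekly_dose` (mg/week), `inr_target`, `clinical_flags`
#'   (semicolon-joined, possibly empty) and one integer alt-allele-count
#'   column per [variant_panel()] site.
#' @examples
#' cfg <- default_cohort_config(n_patients = 200)
#' head(simulate_cohort(cfg))
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  n <- config$n_patients
  withr::with_seed(seed, {
    if (!is.null(config$vkorc1_genotype_freqs)) {
      gA <- sample(0:2, n, replace = TRUE, prob = config$vkorc1_genotype_freqs)
      gT <- gA  # concordant with the dominant G-C / A-T haplotypes
    } else {
      hp <- config$haplotype_freqs_main_pair  # order G-C, G-T, A-C, A-T
      main <- draw_haplotype_pair_genotypes(n, hp,
                                            minor1 = c(0, 0, 1, 1),
                                            minor2 = c(0, 1, 0, 1))
      gA <- main$g1; gT <- main$g2
    }

    sec <- config$ld_pair_secondary
    sec_h <- haplotype_freqs_from_ld(sec$maf_rs17878544, sec$maf_rs7200749,
                                     sec$d_prime)
    secg <- draw_haplotype_pair_genotypes(n, sec_h,
                                          minor1 = c(1, 1, 0, 0),
                                          minor2 = c(1, 0, 1, 0))

    if (!is.null(config$cyp2c9_diplotype_freqs)) {
      dip <- sample(cyp2c9_diplotypes(), n, replace = TRUE,
                    prob = config$cyp2c9_diplotype_freqs)
      c2 <- (dip == "*1*2") + (dip == "*2*3") + 2 * (dip == "*2*2")
      c3 <- (dip == "*1*3") + (dip == "*2*3") + 2 * (dip == "*3*3")
    } else {
      al <- matrix(sample(1:3, 2 * n, replace = TRUE,
                          prob = config$cyp2c9_allele_freqs), nrow = n)
      c2 <- rowSums(al == 2)
      c3 <- rowSums(al == 3)
    }

    g_r12r <- stats::rbinom(n, 2, config$maf_r12r)
    g_d36y <- stats::rbinom(n, 1, config$carrier_freq_d36y)
    g_l128r <- stats::rbinom(n, 1, config$carrier_freq_l128r)

    age <- pmax(18, stats::rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2]))
    bmi <- pmax(15, stats::rnorm(n, config$bmi_mean_sd[1], config$bmi_mean_sd[2]))
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "male", "female")
    inr_target <- ifelse(stats::runif(n) < config$inr_high_target_prop,
                         "2.5-3.5", "2.0-3.0")

    flag_levels <- clinical_flag_levels()
    flag_mat <- matrix(vapply(flag_levels, function(fl) {
      stats::runif(n) < config$confounder_rates[[fl]]
    }, logical(n)), nrow = n, dimnames = list(NULL, flag_levels))
    clinical_flags <- apply(flag_mat, 1, function(row) {
      paste(flag_levels[row], collapse = ";")
    })

    dm <- config$dose_model
    eff <- dm$effects
    dose <- dm$intercept +
      eff[["rs9923231"]] * gA +
      eff[["age"]] * (age - dm$age_center) +
      eff[["cyp2c9"]] * (c2 + 2 * c3) +
      eff[["D36Y"]] * (g_d36y >= 1) +
      eff[["rs55894764"]] * (g_r12r >= 1) +
      eff[["rs7200749"]] * (secg$g2 >= 1) +
      eff[["rs17878544"]] * (secg$g1 >= 1) +
      eff[["L128R"]] * (g_l128r >= 1) +
      eff[["sex"]] * (sex == "male") +
      eff[["bmi"]] * (bmi - config$bmi_mean_sd[1])

    clin <- flag_mat[, setdiff(flag_levels, "no_clinical_data"), drop = FALSE]
    shifted <- rowSums(clin) > 0
    rng <- config$confounder_shift_range
    shift <- ifelse(shifted,
                    sample(c(-1, 1), n, replace = TRUE) *
                      stats::runif(n, rng[1], rng[2]),
                    0)
    dose <- pmax(1, dose + shift + stats::rnorm(n, 0, dm$residual_sd))

    data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = age, sex = sex, bmi = bmi,
      weekly_dose = dose, inr_target = inr_target,
      clinical_flags = clinical_flags,
      rs9923231 = as.integer(gA), rs17878544 = as.integer(secg$g1),
      rs9934438 = as.integer(gT), rs55894764 = as.integer(g_r12r),
      D36Y = as.integer(g_d36y), rs7200749 = as.integer(secg$g2),
      L128R = as.integer(g_l128r),
      rs1799853 = as.integer(c2), rs1057910 = as.integer(c3),
      stringsAsFactors = FALSE
    )
  })
}

#' Overwrite main-pair genotypes of random patients with discordant patterns
#'
#' Plants genotype combinations that cannot be composed from the two dominant
#' rs9923231/rs9934438 haplotypes, for round-trip testing of
#' [find_ld_discordant()]. For `k = 6` (the default patterns) the six
#' published discordant combinations are planted exactly once each; for other
#' `k` the patterns are recycled.
#'
#' @param cohort A cohort data frame from [simulate_cohort()].
#' @param k Number of patients to overwrite (`k <= nrow(cohort)`).
#' @param seed Integer seed for choosing the patients.
#' @param patterns Two-column integer matrix of (rs9923231 A count,
#'   rs9934438 T count) combinations; defaults to the six published patterns.
#' @return List with `cohort` (modified copy) and `planted_ids`.
#' @export
inject_ld_discordant <- function(cohort, k, seed = 17L,
                                 patterns = discordant_patterns()) {
  if (k > nrow(cohort)) {
    stop("k exceeds cohort size (", nrow(cohort), ")", call. = FALSE)
  }
  if (k == 0) return(list(cohort = cohort, planted_ids = character(0)))
  idx <- withr::with_seed(seed, sample.int(nrow(cohort), k))
  rows <- rep_len(seq_len(nrow(patterns)), k)
  cohort$rs9923231[idx] <- patterns[rows, 1]
  cohort$rs9934438[idx] <- patterns[rows, 2]
  list(cohort = cohort, planted_ids = cohort$patient_id[idx])
}

#' The six published discordant genotype patterns
#' @return Integer matrix with columns `rs9923231` (A count) and `rs9934438`
#'   (T count), one row per published patient.
#' @export
discordant_patterns <- function() {
  disc <- published_discordant_patients()
  geno_count <- function(x, het, hom) (x == het) + 2L * (x == hom)
  cbind(rs9923231 = geno_count(disc$rs9923231, "GA", "AA"),
        rs9934438 = geno_count(disc$rs9934438, "CT", "TT"))
}
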