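#' Additive weekly-dose model specification
#'
#' The simulator draws each patient's stable weekly acenocoumarol dose from
#' an additive linear model
#' \deqn{dose = intercept + \sum_j \beta_j x_j + shift_{clinical} + \epsilon,
#'       \quad \epsilon \sim N(0, residual\_sd^2),}
#' truncated below at 1 mg/week. Predictors `x_j` are: rs9923231 A-allele
#' count (0/1/2), age centred at `age_center` (years), the ordinal CYP2C9
#' score (*2 allele count + 2 x *3 allele count), carrier indicators for the
#' rare variants, sex (male = 1) and BMI centred at its mean.
#'
#' @param intercept Expected dose (mg/week) of a wild-type patient of average
#'   age: profile GG / *1*1.
#' @param effects Named numeric vector of per-unit effects (mg/week). Any of
#'   `rs9923231`, `age`, `cyp2c9`, `D36Y`, `rs55894764`, `rs7200749`,
#'   `rs17878544`, `L128R`, `sex`, `bmi`. Omitted predictors get effect 0.
#' @param residual_sd Residual SD (mg/week), must be positive.
#' @param age_center Age (years) at which the intercept applies.
#' @param target_variance_fractions Optional named fractions used by
#'   [calibrate_effects()]; carried along for provenance.
#' @return An object of class `dose_model_spec` (a list).
#' @seealso [calibrate_effects()]
#' @export
dose_model_spec <- function(intercept, effects = numeric(0), residual_sd,
                            age_center = 74,
                            target_variance_fractions = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(residual_sd), length(residual_sd) == 1)
  if (residual_sd <= 0) {
    stop("residual_sd must be > 0", call. = FALSE)
  }
  full <- stats::setNames(numeric(length(dose_predictors())), dose_predictors())
  if (length(effects)) {
    unknown <- setdiff(names(effects), dose_predictors())
    if (length(unknown)) {
      stop("unknown dose-model predictor(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    full[names(effects)] <- effects
  }
  structure(list(intercept = intercept, effects = full,
                 residual_sd = residual_sd, age_center = age_center,
                 target_variance_fractions = target_variance_fractions),
            class = "dose_model_spec")
}

#' Predictor names recognised by the dose model
#' @return Character vector of predictor names.
#' @export
dose_predictors <- function() {
  c("rs9923231", "age", "cyp2c9", "D36Y", "rs55894764",
    "rs7200749", "rs17878544", "L128R", "sex", "bmi")
}

#' Calibrate dose-model effect sizes from target variance fractions
#'
#' Given the fraction of total dose variance each predictor should explain,
#' and treating predictors as mutually independent (which the simulator
#' guarantees), solves `f_j = beta_j^2 Var(x_j) / Var(dose)` for the effect
#' sizes:
#' \deqn{\beta_j = \pm\sqrt{f_j \cdot V / Var(x_j)}, \qquad
#'       residual\_sd = \sqrt{(1 - \sum_j f_j)\, V}.}
#' Signs follow the pharmacology: VKORC1 -1639 A alleles, age and impaired
#' CYP2C9 function lower the required dose; the rare coding/synonymous
#' variants raise it.
#'
#' @param target_variance_fractions Named nonnegative fractions summing to
#'   < 1; names from [dose_predictors()].
#' @param predictor_variances Named positive variances of the predictors, on
#'   their natural scale; must cover every named fraction.
#' @param total_dose_variance Marginal dose variance V (mg^2/week^2).
#' @param intercept Passed through to the returned spec (mg/week).
#' @param age_center Passed through to the returned spec (years).
#' @return A [dose_model_spec()] with calibrated effects and residual SD.
#' @examples
#' calibrate_effects(c(rs9923231 = 0.21), c(rs9923231 = 0.483),
#'                   total_dose_variance = 36, intercept = 18)
#' @export
calibrate_effects <- function(target_variance_fractions, predictor_variances,
                              total_dose_variance, intercept = 18,
                              age_center = 74) {
  f <- target_variance_fractions
  stopifnot(is.numeric(f), !is.null(names(f)),
            is.numeric(predictor_variances), !is.null(names(predictor_variances)))
  if (any(f < 0)) stop("variance fractions must be nonnegative", call. = FALSE)
  if (sum(f) >= 1) {
    stop("variance fractions sum to >= 1: no residual variance left",
         call. = FALSE)
  }
  missing_var <- setdiff(names(f), names(predictor_variances))
  if (length(missing_var)) {
    stop("no predictor variance supplied for: ",
         paste(missing_var, collapse = ", "), call. = FALSE)
  }
  if (any(predictor_variances[names(f)] <= 0)) {
    stop("predictor variances must be > 0", call. = FALSE)
  }
  dose_lowering <- c("rs9923231", "age", "cyp2c9", "sex", "bmi")
  sgn <- ifelse(names(f) %in% dose_lowering, -1, 1)
  beta <- sgn * sqrt(f * total_dose_variance / predictor_variances[names(f)])
  dose_model_spec(
    intercept = intercept,
    effects = stats::setNames(as.numeric(beta), names(f)),
    residual_sd = sqrt((1 - sum(f)) * total_dose_variance),
    age_center = age_center,
    target_variance_fractions = f
  )
}

#' Build a cohort simulation configuration
#'
#' Collects and validates every population quantity the simulator needs. Use
#' [default_cohort_config()] for a configuration calibrated to the published
#' cohort; `cohort_config()` is the validating constructor.
#'
#' @param n_patients Cohort size (>= 1).
#' @param seed Integer seed; every stochastic operation is reproducible.
#' @param haplotype_freqs_main_pair Probabilities of the four
#'   rs9923231/rs9934438 haplotypes, named `G-C`, `G-T`, `A-C`, `A-T`;
#'   must sum to 1.
#' @param ld_pair_secondary List with `maf_rs17878544`, `maf_rs7200749` and
#'   `d_prime` for the partially linked promoter/coding pair.
#' @param maf_r12r Minor allele frequency of rs55894764.
#' @param carrier_freq_d36y,carrier_freq_l128r Carrier probabilities of the
#'   two resistance missense variants (heterozygous carriers).
#' @param cyp2c9_allele_freqs Probabilities of alleles `*1`, `*2`, `*3`
#'   (named); must sum to 1.
#' @param vkorc1_genotype_freqs Optional named probabilities of genotypes
#'   `GG`, `GA`, `AA`. When given, the rs9923231 genotype is drawn from these
#'   marginal frequencies directly (rs9934438 is set to the concordant
#'   genotype) instead of from random haplotype pairing; useful when matching
#'   observed genotype counts that deviate slightly from Hardy-Weinberg.
#' @param cyp2c9_diplotype_freqs Optional named probabilities of the six
#'   diplotypes; same rationale.
#' @param age_mean_sd,bmi_mean_sd Length-2 numeric `c(mean, sd)`.
#' @param sex_ratio Proportion male.
#' @param inr_high_target_prop Proportion of patients titrated to the higher
#'   2.5-3.5 INR target range (the rest use 2.0-3.0).
#' @param dose_model A [dose_model_spec()].
#' @param confounder_rates Named per-category probabilities over
#'   [clinical_flag_levels()].
#' @param confounder_shift_range Length-2 positive range `c(lo, hi)` of the
#'   absolute dose shift (mg/week) applied, with random sign, to patients
#'   carrying at least one clinical condition flag.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed,
                          haplotype_freqs_main_pair,
                          ld_pair_secondary,
                          maf_r12r,
                          carrier_freq_d36y, carrier_freq_l128r,
                          cyp2c9_allele_freqs,
                          vkorc1_genotype_freqs = NULL,
                          cyp2c9_diplotype_freqs = NULL,
                          age_mean_sd = c(74, 10),
                          bmi_mean_sd = c(29.5, 7.4),
                          sex_ratio = 0.49,
                          inr_high_target_prop = 0.10,
                          dose_model,
                          confounder_rates,
                          confounder_shift_range = c(6, 12)) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    haplotype_freqs_main_pair = haplotype_freqs_main_pair,
    ld_pair_secondary = ld_pair_secondary,
    maf_r12r = maf_r12r,
    carrier_freq_d36y = carrier_freq_d36y,
    carrier_freq_l128r = carrier_freq_l128r,
    cyp2c9_allele_freqs = cyp2c9_allele_freqs,
    vkorc1_genotype_freqs = vkorc1_genotype_freqs,
    cyp2c9_diplotype_freqs = cyp2c9_diplotype_freqs,
    age_mean_sd = age_mean_sd, bmi_mean_sd = bmi_mean_sd,
    sex_ratio = sex_ratio, inr_high_target_prop = inr_high_target_prop,
    dose_model = dose_model,
    confounder_rates = confounder_rates,
    confounder_shift_range = confounder_shift_range
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

check_prob_vector <- function(x, nm, expected_names = NULL, tol = 1e-12) {
  if (!is.numeric(x) || any(x < 0)) {
    stop(nm, " must be a nonnegative probability vector", call. = FALSE)
  }
  if (!is.null(expected_names) && !setequal(names(x), expected_names)) {
    stop(nm, " must be named: ", paste(expected_names, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop(nm, " must sum to 1 (got ", format(sum(x), digits = 15), ")",
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a cohort configuration
#' @param config A `cohort_config` list.
#' @return The config, invisibly; stops on the first violated invariant.
#' @export
validate_cohort_config <- function(config) {
  if (config$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  check_prob_vector(config$haplotype_freqs_main_pair,
                    "haplotype_freqs_main_pair",
                    c("G-C", "G-T", "A-C", "A-T"))
  check_prob_vector(config$cyp2c9_allele_freqs, "cyp2c9_allele_freqs",
                    c("*1", "*2", "*3"))
  if (!is.null(config$vkorc1_genotype_freqs)) {
    check_prob_vector(config$vkorc1_genotype_freqs, "vkorc1_genotype_freqs",
                      vkorc1_genotypes())
  }
  if (!is.null(config$cyp2c9_diplotype_freqs)) {
    check_prob_vector(config$cyp2c9_diplotype_freqs, "cyp2c9_diplotype_freqs",
                      cyp2c9_diplotypes())
  }
  sec <- config$ld_pair_secondary
  stopifnot(is.list(sec))
  for (p in c("maf_rs17878544", "maf_rs7200749")) {
    if (is.null(sec[[p]]) || sec[[p]] <= 0 || sec[[p]] >= 1) {
      stop("ld_pair_secondary$", p, " must be in (0, 1)", call. = FALSE)
    }
  }
  if (sec$d_prime < 0 || sec$d_prime > 1) {
    stop("ld_pair_secondary$d_prime must be in [0, 1]", call. = FALSE)
  }
  for (p in c("maf_r12r", "carrier_freq_d36y", "carrier_freq_l128r",
              "sex_ratio", "inr_high_target_prop")) {
    if (config[[p]] < 0 || config[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (!inherits(config$dose_model, "dose_model_spec")) {
    stop("dose_model must be a dose_model_spec", call. = FALSE)
  }
  f <- config$dose_model$target_variance_fractions
  if (!is.null(f) && sum(f) >= 1) {
    stop("dose-model variance fractions sum to >= 1", call. = FALSE)
  }
  rates <- config$confounder_rates
  if (!setequal(names(rates), clinical_flag_levels())) {
    stop("confounder_rates must be named over clinical_flag_levels()",
         call. = FALSE)
  }
  if (any(rates < 0 | rates > 1)) {
    stop("confounder_rates must be probabilities", call. = FALSE)
  }
  rng <- config$confounder_shift_range
  if (length(rng) != 2 || any(rng < 0) || rng[1] > rng[2]) {
    stop("confounder_shift_range must be c(lo, hi) with 0 <= lo <= hi",
         call. = FALSE)
  }
  invisible(config)
}

#' Default configuration calibrated to the published cohort
#'
#' Every number here is derived from the published summary tables (see
#' [published_profile_table()] and friends):
#' * Main-pair haplotype frequencies from the joint rs9923231/rs9934438
#'   genotype table (profile-table marginals plus the six published
#'   discordant patients), with double heterozygotes phased to the dominant
#'   G-C / A-T configuration.
#' * CYP2C9 allele frequencies from diplotype counts; rare-variant carrier
#'   frequencies and the secondary-pair allele frequencies from the published
#'   whole-sample genotype counts.
#' * Dose-model effects from [calibrate_effects()] with total dose variance
#'   36 mg^2/week^2 (whole-sample dose 14 +/- 6) and variance fractions from
#'   the published stepwise ladder: the first three increments as printed
#'   (0.210, 0.130, 0.051) and the remaining 0.009 split between D36Y and
#'   rs55894764 in the ratio of their squared final-model standardized
#'   coefficients, which reconciles the ladder with the published entry
#'   order (see the methods vignette).
#' * Clinical-confounder rates from the published exclusion tally over the
#'   cohort size; their dose-shift variance is folded into the residual so
#'   the marginal dose variance stays at the calibration target.
#'
#' @param n_patients Cohort size (default: published cohort size 3949).
#' @param seed Default seed 17.
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(n_patients = 3949, seed = 17) {
  tab1 <- published_profile_table()
  n_total <- sum(tab1$n)

  ## joint rs9923231/rs9934438 genotype table: concordant counts from the
  ## profile-table VKORC1 marginals minus the six published discordant patients
  vk_marg <- tapply(tab1$n, tab1$vkorc1, sum)[vkorc1_genotypes()]
  disc <- published_discordant_patients()
  joint <- matrix(0, 3, 3, dimnames = list(vkorc1_genotypes(), c("CC", "CT", "TT")))
  for (i in seq_len(nrow(disc))) {
    joint[disc$rs9923231[i], disc$rs9934438[i]] <-
      joint[disc$rs9923231[i], disc$rs9934438[i]] + 1
  }
  joint["GG", "CC"] <- vk_marg[["GG"]] - sum(joint["GG", ])
  joint["GA", "CT"] <- vk_marg[["GA"]] - sum(joint["GA", ])
  joint["AA", "TT"] <- vk_marg[["AA"]] - sum(joint["AA", ])
  ## chromosome counting with double heterozygotes phased G-C / A-T (the
  ## dominant configuration; identical to the EM solution for this table)
  hap_counts <- c(
    "G-C" = 2 * joint["GG", "CC"] + joint["GG", "CT"] + joint["GA", "CC"] +
      joint["GA", "CT"],
    "G-T" = 2 * joint["GG", "TT"] + joint["GG", "CT"] + joint["GA", "TT"],
    "A-C" = 2 * joint["AA", "CC"] + joint["GA", "CC"] + joint["AA", "CT"],
    "A-T" = 2 * joint["AA", "TT"] + joint["AA", "CT"] + joint["GA", "TT"] +
      joint["GA", "CT"]
  )
  hap_freqs <- hap_counts / (2 * n_total)

  cyp_counts <- tapply(tab1$n, tab1$cyp2c9, sum)[cyp2c9_diplotypes()]
  allele_counts <- c(
    "*1" = 2 * cyp_counts[["*1*1"]] + cyp_counts[["*1*2"]] + cyp_counts[["*1*3"]],
    "*2" = 2 * cyp_counts[["*2*2"]] + cyp_counts[["*1*2"]] + cyp_counts[["*2*3"]],
    "*3" = 2 * cyp_counts[["*3*3"]] + cyp_counts[["*1*3"]] + cyp_counts[["*2*3"]]
  )
  cyp_freqs <- allele_counts / (2 * n_total)

  vt <- published_variant_table()
  row_of <- function(id) vt[vt$variant_id == id, ]
  maf_of <- function(id) {
    r <- row_of(id)
    (r$n_het + 2 * r$n_hom) / (2 * (r$n_ref + r$n_het + r$n_hom))
  }
  d36y <- row_of("D36Y")

  ladder <- published_stepwise_ladder()
  incr <- diff(c(0, ladder$cumulative_r2))
  names(incr) <- ladder$predictor
  late <- sum(incr[c("D36Y", "rs55894764")])
  w <- ladder$beta_standardized[match(c("D36Y", "rs55894764"), ladder$predictor)]^2
  fractions <- c(incr[c("rs9923231", "age", "cyp2c9")],
                 late * w / sum(w))
  names(fractions) <- c("rs9923231", "age", "cyp2c9", "D36Y", "rs55894764")

  p_a <- sum(hap_freqs[c("A-C", "A-T")])
  p2 <- cyp_freqs[["*2"]]; p3 <- cyp_freqs[["*3"]]
  carrier_d36y <- (d36y$n_het + d36y$n_hom) / (d36y$n_ref + d36y$n_het + d36y$n_hom)
  maf_r12r <- maf_of("rs55894764")
  carrier_r12r <- 1 - (1 - maf_r12r)^2
  pred_var <- c(
    rs9923231 = 2 * p_a * (1 - p_a),
    age = 100,
    cyp2c9 = 2 * (p2 * (1 - p2) + 4 * p3 * (1 - p3) - 4 * p2 * p3),
    D36Y = carrier_d36y * (1 - carrier_d36y),
    rs55894764 = carrier_r12r * (1 - carrier_r12r)
  )
  total_var <- d36y$dose_sd_noncarrier^2
  model <- calibrate_effects(fractions, pred_var, total_var,
                             intercept = tab1$dose_mean[tab1$profile_id == 1],
                             age_center = 74)

  rates <- published_exclusion_counts() / n_total
  shift_range <- c(6, 12)
  ## fold the confounder shift variance into the residual so the marginal
  ## dose variance stays at total_var (shift is mean-zero)
  clin <- setdiff(clinical_flag_levels(), "no_clinical_data")
  p_any <- 1 - prod(1 - rates[clin])
  # E[U(lo,hi)^2] = (lo^2 + lo*hi + hi^2)/3; shift has random sign, mean 0
  shift_var <- p_any * (shift_range[1]^2 + shift_range[1] * shift_range[2] +
                          shift_range[2]^2) / 3
  resid_var <- model$residual_sd^2 - shift_var
  if (resid_var <= 0) stop("confounder shifts exceed residual variance budget")
  model$residual_sd <- sqrt(resid_var)

  cohort_config(
    n_patients = n_patients, seed = seed,
    haplotype_freqs_main_pair = hap_freqs,
    ld_pair_secondary = list(maf_rs17878544 = maf_of("rs17878544"),
                             maf_rs7200749 = maf_of("rs7200749"),
                             d_prime = 0.99),
    maf_r12r = maf_r12r,
    carrier_freq_d36y = carrier_d36y,
    carrier_freq_l128r = 1 / n_total,
    cyp2c9_allele_freqs = cyp_freqs,
    dose_model = model,
    confounder_rates = rates
  )
}

#' Read or write a cohort configuration as YAML
#'
#' @param path File path.
#' @param config A `cohort_config`.
#' @return `read_cohort_config()`: a validated `cohort_config`;
#'   `write_cohort_config()`: `path`, invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dm <- raw$dose_model
  raw$dose_model <- dose_model_spec(
    intercept = dm$intercept,
    effects = unlist(dm$effects),
    residual_sd = dm$residual_sd,
    age_center = if (is.null(dm$age_center)) 74 else dm$age_center,
    target_variance_fractions =
      if (is.null(dm$target_variance_fractions)) NULL
      else unlist(dm$target_variance_fractions)
  )
  for (nm in c("haplotype_freqs_main_pair", "cyp2c9_allele_freqs",
               "vkorc1_genotype_freqs", "cyp2c9_diplotype_freqs",
               "confounder_rates")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(cohort_config, raw[setdiff(names(raw), character(0))])
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  out <- unclass(config)
  out$dose_model <- unclass(out$dose_model)
  out$dose_model$effects <- as.list(out$dose_model$effects)
  if (!is.null(out$dose_model$target_variance_fractions)) {
    out$dose_model$target_variance_fractions <-
      as.list(out$dose_model$target_variance_fractions)
  }
  for (nm in c("haplotype_freqs_main_pair", "cyp2c9_allele_freqs",
               "vkorc1_genotype_freqs", "cyp2c9_diplotype_freqs",
               "confounder_rates")) {
    if (!is.null(out[[nm]])) out[[nm]] <- as.list(out[[nm]])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
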