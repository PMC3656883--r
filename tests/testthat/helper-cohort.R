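# small, fast configurations used across tests

# perfect main-pair LD, no confounders, simple dose model
tiny_config <- function(n = 200, seed = 1,
                        effects = c(rs9923231 = -4),
                        residual_sd = 2,
                        confounder_rates = NULL,
                        ...) {
  rates <- setNames(rep(0, length(clinical_flag_levels())),
                    clinical_flag_levels())
  if (!is.null(confounder_rates)) rates[names(confounder_rates)] <- confounder_rates
  cohort_config(
    n_patients = n, seed = seed,
    haplotype_freqs_main_pair = c("G-C" = 0.6, "G-T" = 0, "A-C" = 0, "A-T" = 0.4),
    ld_pair_secondary = list(maf_rs17878544 = 0.02, maf_rs7200749 = 0.01,
                             d_prime = 0.99),
    maf_r12r = 0.026,
    carrier_freq_d36y = 0.05, carrier_freq_l128r = 0.01,
    cyp2c9_allele_freqs = c("*1" = 0.76, "*2" = 0.17, "*3" = 0.07),
    dose_model = dose_model_spec(intercept = 18, effects = effects,
                                 residual_sd = residual_sd),
    confounder_rates = rates,
    ...
  )
}

# minimal hand-built cohort for unit tests that bypass the simulator
manual_cohort <- function(dose, rs9923231 = 1, c2 = 0, c3 = 0, flags = "",
                          id = sprintf("M%03d", seq_along(dose))) {
  n <- length(dose)
  data.frame(
    patient_id = id,
    age = rep(70, n), sex = rep("female", n), bmi = rep(27, n),
    weekly_dose = dose, inr_target = rep("2.0-3.0", n),
    clinical_flags = rep_len(flags, n),
    rs9923231 = rep_len(rs9923231, n), rs17878544 = 0L, rs9934438 = 0L,
    rs55894764 = 0L, D36Y = 0L, rs7200749 = 0L, L128R = 0L,
    rs1799853 = rep_len(c2, n), rs1057910 = rep_len(c3, n),
    stringsAsFactors = FALSE
  )
}
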