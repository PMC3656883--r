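test_that("cohorts are byte-identical for a fixed seed", {
  cfg <- tiny_config(n = 300)
  expect_identical(simulate_cohort(cfg, seed = 9), simulate_cohort(cfg, seed = 9))
  # and the seed matters
  expect_false(identical(simulate_cohort(cfg, seed = 9),
                         simulate_cohort(cfg, seed = 10)))
})

test_that("simulated frequencies converge to configured values", {
  cfg <- default_cohort_config(n_patients = 1e5, seed = 2)
  coh <- simulate_cohort(cfg)
  binom_ci <- function(p, n) 4 * sqrt(p * (1 - p) / n)  # ~4 sigma
  p_a <- sum(cfg$haplotype_freqs_main_pair[c("A-C", "A-T")])
  expect_equal(mean(coh$rs9923231) / 2, p_a, tolerance = binom_ci(p_a, 2e5) / p_a)
  expect_equal(mean(coh$D36Y >= 1), cfg$carrier_freq_d36y,
               tolerance = binom_ci(cfg$carrier_freq_d36y, 1e5) /
                 cfg$carrier_freq_d36y)
  expect_equal(mean(coh$rs55894764) / 2, cfg$maf_r12r,
               tolerance = binom_ci(cfg$maf_r12r, 2e5) / cfg$maf_r12r)
  p3 <- cfg$cyp2c9_allele_freqs[["*3"]]
  expect_equal(mean(coh$rs1057910) / 2, p3, tolerance = binom_ci(p3, 2e5) / p3)
})

test_that("main-pair r2 is near 1 when recombinant haplotype mass is tiny", {
  cfg <- default_cohort_config(n_patients = 1e5, seed = 4)
  # recombinant mass in the default calibration is ~0.00076
  expect_lt(sum(cfg$haplotype_freqs_main_pair[c("G-T", "A-C")]), 0.001)
  coh <- simulate_cohort(cfg)
  est <- em_haplotypes(two_locus_table(coh, c("rs9923231", "rs9934438")))
  expect_gt(ld_stats(est)$r_squared, 0.99)
})

test_that("with zero effects and vanishing noise every dose is the intercept", {
  cfg <- tiny_config(n = 50, effects = numeric(0), residual_sd = 1e-9)
  coh <- simulate_cohort(cfg, seed = 1)
  expect_equal(coh$weekly_dose, rep(18, 50), tolerance = 1e-6)
})

test_that("single-predictor regression recovers each designed variance fraction", {
  cfg <- default_cohort_config(n_patients = 1e5, seed = 6)
  coh <- simulate_cohort(cfg)
  dat <- build_design(coh, c("rs9923231", "age", "cyp2c9"))
  f <- cfg$dose_model$target_variance_fractions
  for (pred in c("rs9923231", "age", "cyp2c9")) {
    r2 <- summary(stats::lm(stats::reformulate(pred, "weekly_dose"),
                            data = dat))$r.squared
    expect_equal(r2, f[[pred]], tolerance = 0.02 / f[[pred]],
                 label = paste("R2 of", pred))
  }
})

test_that("genotype-frequency overrides drive the marginal distributions", {
  cfg <- tiny_config(n = 2e4,
                     vkorc1_genotype_freqs = c(GG = 0.35, GA = 0.49, AA = 0.16),
                     cyp2c9_diplotype_freqs = c("*1*1" = 0.58, "*1*2" = 0.25,
                                                "*1*3" = 0.11, "*2*2" = 0.03,
                                                "*2*3" = 0.02, "*3*3" = 0.01))
  coh <- simulate_cohort(cfg, seed = 11)
  expect_equal(mean(coh$rs9923231 == 1), 0.49, tolerance = 0.03)
  expect_equal(mean(coh$rs1799853 == 0 & coh$rs1057910 == 0), 0.58,
               tolerance = 0.03)
  # override keeps the pair concordant with the dominant haplotypes
  expect_identical(coh$rs9923231, coh$rs9934438)
})

test_that("clinical flags appear at the configured rates", {
  cfg <- tiny_config(n = 4e4,
                     confounder_rates = c(interacting_drugs = 0.01,
                                          obesity = 0.005))
  coh <- simulate_cohort(cfg, seed = 3)
  flags <- parse_clinical_flags(coh$clinical_flags)
  expect_equal(mean(vapply(flags, function(f) "interacting_drugs" %in% f,
                           logical(1))), 0.01, tolerance = 0.25)
  expect_equal(mean(vapply(flags, function(f) "obesity" %in% f, logical(1))),
               0.005, tolerance = 0.35)
})

test_that("inject_ld_discordant plants and reports exactly k patients", {
  cfg <- tiny_config(n = 100)
  coh <- simulate_cohort(cfg, seed = 2)
  expect_identical(inject_ld_discordant(coh, 0)$cohort, coh)
  expect_error(inject_ld_discordant(coh, 101), "exceeds cohort size")
  res <- inject_ld_discordant(coh, 6, seed = 5)
  expect_length(res$planted_ids, 6)
  planted <- res$cohort[match(res$planted_ids, res$cohort$patient_id), ]
  pat <- discordant_patterns()
  expect_setequal(paste(planted$rs9923231, planted$rs9934438),
                  paste(pat[, 1], pat[, 2]))
  # untouched patients unchanged
  rest <- setdiff(coh$patient_id, res$planted_ids)
  expect_identical(res$cohort[match(rest, res$cohort$patient_id), ],
                   coh[match(rest, coh$patient_id), ])
})

test_that("haplotype_freqs_from_ld hits the target D-prime", {
  h <- haplotype_freqs_from_ld(0.0217, 0.0115, 0.99)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  ld <- ld_stats(c(h11 = h[["h11"]], h10 = h[["h10"]],
                   h01 = h[["h01"]], h00 = h[["h00"]]))
  expect_equal(ld$D_prime, 0.99, tolerance = 1e-9)
  # with these allele frequencies D' = 0.99 pins r2 at ~0.514
  expect_equal(ld$r_squared, 0.514, tolerance = 1e-3)
})
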