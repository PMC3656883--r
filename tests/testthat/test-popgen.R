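test_that("carrier fraction and MAF follow from genotype counts", {
  # published R12R-style counts
  f <- carrier_and_allele_freq(3744, 198, 4)
  expect_equal(f$carrier, 202 / 3946)
  expect_equal(f$maf, 206 / 7892)
  expect_identical(carrier_and_allele_freq(100, 0, 0),
                   list(carrier = 0, maf = 0))
  expect_identical(carrier_and_allele_freq(0, 0, 50),
                   list(carrier = 1, maf = 1))
  expect_error(carrier_and_allele_freq(0, 0, 0), "undefined")
})

test_that("EM finds perfect LD and linkage equilibrium exactly", {
  # only AB/AB, ab/ab and AB/ab individuals: all mass on two haplotypes
  perfect <- matrix(0, 3, 3); perfect[1, 1] <- 5; perfect[3, 3] <- 4
  perfect[2, 2] <- 3
  est <- em_haplotypes(perfect)
  expect_true(est$converged)
  expect_equal(unname(est$frequencies[c("h10", "h01")]), c(0, 0),
               tolerance = 1e-6)
  ld <- ld_stats(est)
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r_squared, 1, tolerance = 1e-6)

  # counts proportional to independent allele draws: equilibrium, D = 0
  eq <- outer(c(1, 2, 1), c(1, 2, 1)) * 4
  est_eq <- em_haplotypes(eq)
  ld_eq <- ld_stats(est_eq)
  expect_equal(ld_eq$D, 0, tolerance = 1e-12)
  expect_equal(ld_eq$r_squared, 0, tolerance = 1e-12)
})

test_that("EM rejects monomorphic loci and empty tables", {
  mono <- matrix(0, 3, 3); mono[1, 2] <- 10
  expect_error(em_haplotypes(mono), "monomorphic")
  expect_error(em_haplotypes(matrix(0, 3, 3)), "empty")
  expect_error(ld_stats(c(h11 = 0, h10 = 0, h01 = 0, h00 = 1)), "degenerate")
})

test_that("the reconstructed near-perfect pair gives the expected LD", {
  # whole-sample joint table: concordant marginals plus the six published
  # discordant patients
  tab <- matrix(c(1366, 1, 0,
                  1, 1936, 2,
                  0, 2, 641), 3, 3, byrow = TRUE)
  est <- em_haplotypes(tab)
  # frozen from the 1-D grid-search oracle (helper-oracle.R)
  expect_equal(unname(est$frequencies["h11"]), 0.407951, tolerance = 1e-5)
  ld <- ld_stats(est)
  expect_equal(ld$D_prime, 0.99843, tolerance = 1e-4)
  expect_equal(ld$r_squared, 0.99686, tolerance = 1e-4)
})

test_that("EM matches the grid-search likelihood oracle on random tables", {
  withr::with_seed(101, {
    for (i in 1:60) {
      tab <- random_polymorphic_table()
      expect_true(em_haplotypes(tab)$converged)
      expect_matches_oracle(tab, label = paste("table", i))
    }
  })
})

test_that("haplotype margins reproduce the observed allele frequencies", {
  withr::with_seed(55, {
    for (i in 1:20) {
      tab <- random_polymorphic_table()
      n <- sum(tab)
      est <- em_haplotypes(tab)
      h <- est$frequencies
      p1_obs <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
      p2_obs <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
      expect_equal(unname(h[["h11"]] + h[["h10"]]), p1_obs, tolerance = 1e-9)
      expect_equal(unname(h[["h11"]] + h[["h01"]]), p2_obs, tolerance = 1e-9)
    }
  })
})

test_that("ld_stats closed forms", {
  ld <- ld_stats(c(h11 = 0.5, h10 = 0, h01 = 0, h00 = 0.5))
  expect_equal(ld$D, 0.25)
  expect_equal(ld$D_prime, 1)
  expect_equal(ld$r_squared, 1)
  ld0 <- ld_stats(c(h11 = 0.25, h10 = 0.25, h01 = 0.25, h00 = 0.25))
  expect_identical(unlist(ld0), c(D = 0, D_prime = 0, r_squared = 0))
})

test_that("discordance screen flags exactly the non-composable genotypes", {
  cfg <- tiny_config(n = 200)   # zero recombinant mass: fully concordant
  coh <- simulate_cohort(cfg, seed = 14)
  expect_length(find_ld_discordant(coh), 0)

  # dominance established on the clean cohort, as in a whole-sample analysis
  est <- em_haplotypes(two_locus_table(coh))
  planted <- inject_ld_discordant(coh, 6, seed = 3)
  found <- find_ld_discordant(planted$cohort, estimate = est)
  expect_setequal(found, planted$planted_ids)

  # a doubly discordant GG/TT patient is flagged too
  coh2 <- coh
  coh2$rs9923231[10] <- 0L; coh2$rs9934438[10] <- 2L
  expect_identical(find_ld_discordant(coh2), coh2$patient_id[10])

  # missing genotypes are never flagged
  coh3 <- planted$cohort
  coh3$rs9934438[match(planted$planted_ids[1], coh3$patient_id)] <- NA
  expect_setequal(find_ld_discordant(coh3, estimate = est),
                  planted$planted_ids[-1])
})

test_that("discordance screen refuses weakly linked pairs", {
  cfg <- tiny_config(n = 50)
  coh <- simulate_cohort(cfg, seed = 4)
  weak <- structure(list(frequencies = c(h11 = 0.3, h10 = 0.2,
                                         h01 = 0.2, h00 = 0.3)),
                    class = "haplotype_estimate")
  expect_error(find_ld_discordant(coh, estimate = weak), "not applicable")
})

test_that("planted discordants are recovered across k up to 10", {
  cfg <- tiny_config(n = 300)
  coh <- simulate_cohort(cfg, seed = 21)
  est <- em_haplotypes(two_locus_table(coh))
  for (k in c(1, 4, 10)) {
    planted <- inject_ld_discordant(coh, k, seed = k)
    expect_setequal(find_ld_discordant(planted$cohort, estimate = est),
                    planted$planted_ids)
  }
})
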