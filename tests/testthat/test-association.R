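test_that("identical group summaries give t = 0, p = 1", {
  out <- t_test_from_summaries(10, 14, 5, 10, 14, 5)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  out_p <- t_test_from_summaries(10, 14, 5, 10, 14, 5, variant = "pooled")
  expect_equal(out_p$p, 1)
})

test_that("Welch test on the published D36Y summaries", {
  # frozen from direct evaluation of the Welch formulas
  out <- t_test_from_summaries(14, 22, 9, 3935, 14, 6)
  expect_equal(out$t, 3.3233, tolerance = 1e-4)
  expect_equal(out$df, 13.041, tolerance = 1e-3)
  expect_equal(out$p, 0.00547, tolerance = 1e-3)
})

test_that("Welch test on the published R12R summaries is below the printed bound", {
  out <- t_test_from_summaries(202, 16, 6, 3744, 14, 5)
  expect_lt(out$p, 0.001)
})

test_that("summary-based tests agree with stats::t.test on raw data", {
  # build raw groups with exactly the requested summaries
  make_group <- function(n, m, s) {
    x <- scale(stats::rnorm(n))  # mean 0, sd 1 exactly
    as.numeric(m + s * x)
  }
  withr::with_seed(31, {
    for (i in 1:5) {
      n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
      m1 <- stats::runif(1, 10, 20); m0 <- stats::runif(1, 10, 20)
      s1 <- stats::runif(1, 2, 8); s0 <- stats::runif(1, 2, 8)
      x1 <- make_group(n1, m1, s1); x0 <- make_group(n0, m0, s0)
      w <- t_test_from_summaries(n1, m1, s1, n0, m0, s0)
      ref <- stats::t.test(x1, x0)
      expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
      expect_equal(w$p, ref$p.value, tolerance = 1e-9)
      pl <- t_test_from_summaries(n1, m1, s1, n0, m0, s0, variant = "pooled")
      ref_p <- stats::t.test(x1, x0, var.equal = TRUE)
      expect_equal(pl$p, ref_p$p.value, tolerance = 1e-9)
    }
  })
})

test_that("t is antisymmetric under group swap, p invariant", {
  a <- t_test_from_summaries(12, 20, 6, 30, 14, 5)
  b <- t_test_from_summaries(30, 14, 5, 12, 20, 6)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
})

test_that("group-size preconditions are enforced", {
  expect_error(t_test_from_summaries(1, 20, 6, 30, 14, 5), "at least 2")
  coh <- manual_cohort(rep(14, 20))
  coh$D36Y <- 1L  # everyone a carrier
  expect_error(carrier_association(coh, "D36Y"), "insufficient data")
  expect_error(carrier_association(coh, "nope"), "no genotype column")
})

test_that("carrier_association recovers a planted dose effect", {
  cfg <- default_cohort_config(n_patients = 3949)
  hits <- vapply(1:12, function(s) {
    coh <- simulate_cohort(cfg, seed = 100 + s)
    res <- carrier_association(coh, "D36Y")
    res$mean_carrier > res$mean_noncarrier && res$p_value < 0.05
  }, logical(1))
  # designed effect is ~+8 mg/week in ~14 carriers: high power
  expect_gte(mean(hits), 0.8)
})

test_that("carrier_association matches a raw t.test (dual route)", {
  cfg <- tiny_config(n = 400, effects = c(D36Y = 5), residual_sd = 4)
  coh <- simulate_cohort(cfg, seed = 77)
  res <- carrier_association(coh, "D36Y")
  ref <- stats::t.test(weekly_dose ~ D36Y >= 1, data = coh)
  # t.test orders groups FALSE, TRUE: sign flips
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
  expect_equal(res$t_statistic, -unname(ref$statistic), tolerance = 1e-9)
})

test_that("pearson_r closed forms and agreement with cor.test", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(x, x)$p, 0)
  expect_error(pearson_r(x, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
  withr::with_seed(13, {
    a <- stats::rnorm(50); b <- 0.3 * a + stats::rnorm(50)
  })
  mine <- pearson_r(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})
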