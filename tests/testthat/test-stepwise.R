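test_that("an exact linear predictor enters first and alone", {
  coh <- manual_cohort(rep(10, 80))
  withr::with_seed(5, {
    coh$rs9923231 <- sample(0:2, 80, replace = TRUE)
    coh$age <- stats::rnorm(80, 70, 10)
    coh$bmi <- stats::rnorm(80, 29, 6)
  })
  coh$weekly_dose <- 20 - 4 * coh$rs9923231
  steps <- suppressWarnings(
    stepwise_fit(coh, design_spec(c("rs9923231", "age", "bmi"))))
  expect_identical(steps$predictor[1], "rs9923231")
  expect_equal(steps$cumulative_r2[1], 1, tolerance = 1e-9)
  expect_identical(nrow(steps), 1L)
})

test_that("pure-noise candidates enter at roughly the nominal family rate", {
  k <- 3
  entered <- vapply(1:200, function(s) {
    withr::with_seed(4000 + s, {
      coh <- manual_cohort(stats::rnorm(60, 14, 4))
      coh$age <- stats::rnorm(60, 70, 10)
      coh$bmi <- stats::rnorm(60, 29, 6)
      coh$sex <- sample(c("male", "female"), 60, replace = TRUE)
    })
    nrow(stepwise_fit(coh, design_spec(c("age", "bmi", "sex"),
                                       p_enter = 0.05))) > 0
  }, logical(1))
  expected <- 1 - 0.95^k            # ~0.143
  se <- sqrt(expected * (1 - expected) / 200)
  expect_equal(mean(entered), expected, tolerance = 4 * se / expected)
})

test_that("each R2 increment is the squared partial correlation of the entrant", {
  cfg <- default_cohort_config(n_patients = 2000)
  coh <- simulate_cohort(cfg, seed = 6)
  des <- design_spec(c("rs9923231", "age", "cyp2c9", "D36Y", "rs55894764"))
  steps <- stepwise_fit(coh, des)
  dat <- build_design(coh, des$candidates)
  for (i in seq_len(nrow(steps))) {
    prev <- steps$predictor[seq_len(i - 1)]
    entrant <- steps$predictor[i]
    if (length(prev)) {
      ry <- stats::resid(stats::lm(stats::reformulate(prev, "weekly_dose"), dat))
      rx <- stats::resid(stats::lm(stats::reformulate(prev, entrant), dat))
      prev_r2 <- steps$cumulative_r2[i - 1]
    } else {
      ry <- dat$weekly_dose - mean(dat$weekly_dose)
      rx <- dat[[entrant]] - mean(dat[[entrant]])
      prev_r2 <- 0
    }
    increment <- (1 - prev_r2) * stats::cor(ry, rx)^2
    expect_equal(steps$cumulative_r2[i] - prev_r2, increment,
                 tolerance = 1e-8, label = paste("increment at step", i))
  }
  # ladder is non-decreasing
  expect_true(all(diff(steps$cumulative_r2) >= -1e-12))
})

test_that("orthogonal predictors enter in order of marginal R2", {
  n <- 120
  withr::with_seed(88, {
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n); x3 <- stats::rnorm(n)
  })
  # orthogonalize and standardize
  x2 <- stats::resid(stats::lm(x2 ~ x1))
  x3 <- stats::resid(stats::lm(x3 ~ x1 + x2))
  coh <- manual_cohort(rep(1, n))
  coh$age <- as.numeric(scale(x1))
  coh$bmi <- as.numeric(scale(x2))
  coh$rs9923231 <- as.numeric(scale(x3))  # numeric stand-in, encoder passes it
  withr::with_seed(89, {
    coh$weekly_dose <- 14 + 3 * coh$bmi + 2 * coh$age +
      1.2 * coh$rs9923231 + stats::rnorm(n, 0, 1)
  })
  des <- design_spec(c("age", "bmi", "rs9923231"))
  steps <- stepwise_fit(coh, des)
  marg <- vapply(des$candidates, function(v) {
    summary(stats::lm(stats::reformulate(v, "weekly_dose"),
                      build_design(coh, des$candidates)))$r.squared
  }, numeric(1))
  expect_identical(steps$predictor,
                   names(sort(marg, decreasing = TRUE))[seq_len(nrow(steps))])
})

test_that("collinear candidates are skipped with a warning", {
  cfg <- tiny_config(n = 300, effects = c(rs9923231 = -4, D36Y = 6),
                     residual_sd = 2)
  coh <- simulate_cohort(cfg, seed = 19)
  coh$rs55894764 <- coh$D36Y  # duplicate predictor
  w <- testthat::capture_warnings(
    steps <- stepwise_fit(coh, design_spec(c("rs9923231", "D36Y",
                                             "rs55894764"))))
  expect_true(any(grepl("collinear", w)))
  expect_false(all(c("D36Y", "rs55894764") %in% steps$predictor))
})

test_that("the planted standardized VKORC1 beta is recovered", {
  cfg <- default_cohort_config()
  betas <- vapply(1:10, function(s) {
    coh <- simulate_cohort(cfg, seed = 300 + s)
    steps <- stepwise_fit(coh, design_spec(c("rs9923231", "age", "cyp2c9",
                                             "D36Y", "rs55894764")))
    steps$beta_standardized[steps$predictor == "rs9923231"]
  }, numeric(1))
  expect_equal(mean(betas), -0.461, tolerance = 0.03 / 0.461)
})

test_that("r2_ladder formats to three decimals and rejects empty ladders", {
  steps <- data.frame(step = 1L, predictor = "rs9923231",
                      cumulative_r2 = 0.2104, model_p = 2e-16,
                      beta_standardized = -0.4614, beta_p = 1e-8)
  out <- r2_ladder(steps)
  expect_identical(out$r_squared, "0.210")
  expect_identical(out$p, "<0.001")
  expect_identical(out$beta, "-0.461 (<0.001)")
  expect_error(r2_ladder(steps[0, ]), "empty ladder")
})
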