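#' Specification of the stepwise dose regression
#'
#' @param candidates Candidate predictor names; any of [dose_predictors()].
#'   The default offers the five published predictors plus sex and BMI (which
#'   are expected not to enter).
#' @param p_enter Forward entry threshold on the partial-F p value.
#' @param p_remove Backward removal threshold; must exceed `p_enter`.
#' @return List of class `design_spec`.
#' @export
design_spec <- function(candidates = c("rs9923231", "age", "cyp2c9", "D36Y",
                                       "rs55894764", "sex", "bmi"),
                        p_enter = 0.05, p_remove = 0.10) {
  stopifnot(all(candidates %in% dose_predictors()))
  if (!(p_enter < p_remove)) stop("p_enter must be < p_remove", call. = FALSE)
  structure(list(candidates = candidates, p_enter = p_enter,
                 p_remove = p_remove), class = "design_spec")
}

#' Numeric design matrix for the dose regression
#'
#' Encodes predictors on their analysis scale: rs9923231 as the A-allele
#' count, CYP2C9 as the ordinal score (*2 count + 2 x *3 count), the rare
#' variants as dominant carrier indicators, sex as male = 1, age and BMI as
#' is. Rows with any missing value among the requested columns are dropped
#' (listwise deletion).
#'
#' @param cohort Cohort data frame.
#' @param candidates Predictor names to encode.
#' @return Data frame with `weekly_dose` plus one column per candidate.
#' @export
build_design <- function(cohort, candidates) {
  enc <- list(
    rs9923231 = function(d) d$rs9923231,
    age = function(d) d$age,
    cyp2c9 = function(d) d$rs1799853 + 2 * d$rs1057910,
    D36Y = function(d) as.integer(d$D36Y >= 1),
    rs55894764 = function(d) as.integer(d$rs55894764 >= 1),
    rs7200749 = function(d) as.integer(d$rs7200749 >= 1),
    rs17878544 = function(d) as.integer(d$rs17878544 >= 1),
    L128R = function(d) as.integer(d$L128R >= 1),
    sex = function(d) as.integer(d$sex == "male"),
    bmi = function(d) d$bmi
  )
  stopifnot(all(candidates %in% names(enc)))
  dat <- data.frame(weekly_dose = cohort$weekly_dose)
  for (cand in candidates) dat[[cand]] <- enc[[cand]](cohort)
  dat[stats::complete.cases(dat), , drop = FALSE]
}

#' Forward stepwise additive regression of weekly dose
#'
#' Forward entry of the candidate with the smallest partial-F p value below
#' `p_enter`; after each entry, any included predictor whose p value has
#' drifted above `p_remove` is removed (worst first). Terminates when no
#' candidate can enter. Per-step cumulative R-squared comes from the ordinary
#' least-squares fit after that entry; the reported coefficient of each
#' predictor is its standardized beta in the final model (response and
#' predictors z-scored), as published dose-model summaries do.
#'
#' @param cohort Cohort data frame.
#' @param design A [design_spec()].
#' @return Data frame of class `stepwise_ladder`, one row per entry step:
#'   `step`, `predictor`, `cumulative_r2`, `model_p` (overall F),
#'   `beta_standardized`, `beta_p` (final-model values; NA for a predictor
#'   removed after entering). Zero rows when nothing enters.
#' @export
stepwise_fit <- function(cohort, design = design_spec()) {
  dat <- build_design(cohort, design$candidates)
  k <- length(design$candidates)
  if (nrow(dat) < 10 * k) {
    stop("need at least 10 complete cases per candidate (",
         nrow(dat), " cases for ", k, " candidates)", call. = FALSE)
  }
  included <- character(0)
  pool <- design$candidates
  steps <- list()
  fit <- stats::lm(weekly_dose ~ 1, data = dat)

  repeat {
    collinear <- vapply(pool, function(cand) {
      if (stats::var(dat[[cand]]) == 0) return(TRUE)
      if (!length(included)) return(FALSE)
      r2 <- summary(stats::lm(
        stats::reformulate(included, response = cand), data = dat))$r.squared
      r2 >= 1 - 1e-8
    }, logical(1))
    if (any(collinear)) {
      warning("skipping collinear/constant candidate(s): ",
              paste(pool[collinear], collapse = ", "), call. = FALSE)
      pool <- pool[!collinear]
    }
    usable <- pool
    if (!length(usable)) break
    add <- stats::add1(fit, scope = stats::reformulate(c(included, usable)),
                       test = "F")
    pvals <- stats::setNames(add[["Pr(>F)"]], rownames(add))[usable]
    best <- names(which.min(pvals))
    if (!length(best) || pvals[[best]] >= design$p_enter) break
    included <- c(included, best)
    pool <- setdiff(pool, best)
    fit <- stats::lm(stats::reformulate(included, response = "weekly_dose"),
                     data = dat)
    sm <- summary(fit)
    fs <- sm$fstatistic
    steps[[length(steps) + 1]] <- data.frame(
      step = length(steps) + 1L, predictor = best,
      cumulative_r2 = sm$r.squared,
      model_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
    # backward pass: drop anything whose p has drifted above p_remove
    repeat {
      if (length(included) < 2) break
      dr <- stats::drop1(fit, test = "F")
      dp <- stats::setNames(dr[["Pr(>F)"]], rownames(dr))[included]
      worst <- names(which.max(dp))
      if (dp[[worst]] <= design$p_remove) break
      message("stepwise_fit: removing ", worst, " (p = ",
              signif(dp[[worst]], 3), ")")
      included <- setdiff(included, worst)
      pool <- c(pool, worst)
      fit <- stats::lm(stats::reformulate(included, response = "weekly_dose"),
                       data = dat)
    }
  }

  steps <- if (length(steps)) do.call(rbind, steps) else empty_ladder()[1:4]
  steps$beta_standardized <- rep(NA_real_, nrow(steps))
  steps$beta_p <- rep(NA_real_, nrow(steps))
  if (length(included)) {
    zdat <- as.data.frame(scale(dat[c("weekly_dose", included)]))
    zfit <- stats::lm(stats::reformulate(included, response = "weekly_dose"),
                      data = zdat)
    zs <- summary(zfit)$coefficients
    idx <- match(steps$predictor, included)
    present <- !is.na(idx)
    steps$beta_standardized[present] <- zs[included[idx[present]], "Estimate"]
    steps$beta_p[present] <- zs[included[idx[present]], "Pr(>|t|)"]
  }
  class(steps) <- c("stepwise_ladder", "data.frame")
  steps
}

empty_ladder <- function() {
  steps <- data.frame(step = integer(0), predictor = character(0),
                      cumulative_r2 = numeric(0), model_p = numeric(0),
                      beta_standardized = numeric(0), beta_p = numeric(0),
                      stringsAsFactors = FALSE)
  class(steps) <- c("stepwise_ladder", "data.frame")
  steps
}

#' Format a stepwise ladder for reporting
#'
#' Three-decimal table mirroring the published layout: cumulative R-squared,
#' overall model p, standardized coefficient with its p value.
#'
#' @param steps Output of [stepwise_fit()] with at least one step.
#' @return Data frame of formatted character columns.
#' @export
r2_ladder <- function(steps) {
  if (nrow(steps) == 0) stop("empty ladder: no predictor entered", call. = FALSE)
  fmt_p <- function(p) ifelse(is.na(p), "removed",
                              ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  data.frame(
    predictor = steps$predictor,
    r_squared = sprintf("%.3f", steps$cumulative_r2),
    p = fmt_p(steps$model_p),
    beta = ifelse(is.na(steps$beta_standardized), "removed",
                  sprintf("%.3f (%s)", steps$beta_standardized,
                          fmt_p(steps$beta_p))),
    stringsAsFactors = FALSE
  )
}
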