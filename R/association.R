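#' Two-sample t test from group summary statistics
#'
#' Welch (default): `t = (m1 - m0) / sqrt(s1^2/n1 + s0^2/n0)` with
#' Welch-Satterthwaite degrees of freedom; pooled: classical equal-variance
#' formulas. Two-sided p from the t distribution. Works directly from the
#' published-style (n, mean, SD) summaries, which `stats::t.test` cannot.
#'
#' @param n1,m1,s1 Carrier (or first) group count, mean, SD.
#' @param n0,m0,s0 Comparison group count, mean, SD.
#' @param variant `"welch"` or `"pooled"`.
#' @return List with `t`, `df`, `p`.
#' @examples
#' t_test_from_summaries(14, 22, 9, 3935, 14, 6)  # D36Y-style imbalance
#' @export
t_test_from_summaries <- function(n1, m1, s1, n0, m0, s0,
                                  variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n0 < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  stopifnot(s1 >= 0, s0 >= 0)
  if (variant == "welch") {
    v1 <- s1^2 / n1
    v0 <- s0^2 / n0
    se <- sqrt(v1 + v0)
    if (se == 0) return(list(t = 0, df = n1 + n0 - 2, p = 1))
    t <- (m1 - m0) / se
    df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n0 - 1) * s0^2) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    if (se == 0) return(list(t = 0, df = n1 + n0 - 2, p = 1))
    t <- (m1 - m0) / se
    df <- n1 + n0 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Carrier vs non-carrier dose comparison for one variant
#'
#' Groups patients under the dominant model (>= 1 alt allele = carrier,
#' matching the published "het+hom" grouping), computes per-group dose
#' summaries and delegates to [t_test_from_summaries()]. Patients missing the
#' genotype are dropped (pairwise deletion).
#'
#' @param cohort Cohort data frame.
#' @param variant_id Genotype column name.
#' @param variant t-test variant, `"welch"` (default) or `"pooled"`.
#' @param min_group Minimum patients per group (default 4).
#' @return Data frame row with counts, means, SDs, `t_statistic`, `df`,
#'   `p_value`.
#' @export
carrier_association <- function(cohort, variant_id,
                                variant = c("welch", "pooled"),
                                min_group = 4) {
  variant <- match.arg(variant)
  g <- cohort[[variant_id]]
  if (is.null(g)) stop("no genotype column '", variant_id, "'", call. = FALSE)
  keep <- !is.na(g)
  carrier <- g[keep] >= 1
  dose <- cohort$weekly_dose[keep]
  n1 <- sum(carrier)
  n0 <- sum(!carrier)
  if (n1 < min_group || n0 < min_group) {
    stop("insufficient data for ", variant_id, ": ", n1, " carriers vs ",
         n0, " non-carriers (need >= ", min_group, " each)", call. = FALSE)
  }
  m1 <- mean(dose[carrier]);  s1 <- stats::sd(dose[carrier])
  m0 <- mean(dose[!carrier]); s0 <- stats::sd(dose[!carrier])
  tt <- t_test_from_summaries(n1, m1, s1, n0, m0, s0, variant = variant)
  data.frame(variant_id = variant_id,
             n_carrier = n1, n_noncarrier = n0,
             mean_carrier = m1, mean_noncarrier = m0,
             sd_carrier = s1, sd_noncarrier = s0,
             t_statistic = tt$t, df = tt$df, p_value = tt$p,
             stringsAsFactors = FALSE)
}

#' Carrier association table over several variants
#' @param cohort Cohort data frame.
#' @param variant_ids Genotype column names (default: the five rare/low
#'   frequency VKORC1 variants of the panel that can be tested).
#' @param ... Passed to [carrier_association()].
#' @return Data frame, one row per testable variant; variants failing the
#'   group-size precondition are skipped with a message.
#' @export
association_table <- function(cohort,
                              variant_ids = c("D36Y", "rs55894764",
                                              "rs7200749", "rs17878544"),
                              ...) {
  rows <- lapply(variant_ids, function(v) {
    tryCatch(carrier_association(cohort, v, ...), error = function(e) {
      message("association_table: skipping ", v, " (", conditionMessage(e), ")")
      NULL
    })
  })
  do.call(rbind, rows)
}

#' Pearson product-moment correlation with t-based p value
#'
#' `r = cov(x, y) / (sd(x) sd(y))`; p from `t = r sqrt((n-2)/(1-r^2))` with
#' n - 2 degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length >= 3, NA pairs dropped.
#' @return List with `r`, `n`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, n = n, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, n = n, p = 2 * stats::pt(-abs(t), n - 2))
}
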