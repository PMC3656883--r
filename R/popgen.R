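#' Carrier fraction and minor allele frequency from genotype counts
#'
#' @param n_ref,n_het,n_hom Nonnegative counts of non-carriers, heterozygotes
#'   and alt homozygotes.
#' @return List with `carrier` = (n_het + n_hom) / total and
#'   `maf` = (n_het + 2 n_hom) / (2 total).
#' @examples
#' carrier_and_allele_freq(3744, 198, 4)  # carrier ~5.1%, MAF ~2.6%
#' @export
carrier_and_allele_freq <- function(n_ref, n_het, n_hom) {
  stopifnot(n_ref >= 0, n_het >= 0, n_hom >= 0)
  total <- n_ref + n_het + n_hom
  if (total == 0) stop("no genotyped individuals: frequencies undefined",
                       call. = FALSE)
  list(carrier = (n_het + n_hom) / total,
       maf = (n_het + 2 * n_hom) / (2 * total))
}

#' 3x3 two-locus genotype count table from a cohort
#'
#' Rows index the alt-allele count at the first locus (0/1/2), columns at the
#' second. Patients missing either genotype are dropped (pairwise deletion).
#'
#' @param cohort Cohort data frame.
#' @param pair Character vector of two variant column names.
#' @return 3x3 integer matrix.
#' @export
two_locus_table <- function(cohort, pair = c("rs9923231", "rs9934438")) {
  stopifnot(length(pair) == 2, all(pair %in% names(cohort)))
  g1 <- cohort[[pair[1]]]
  g2 <- cohort[[pair[2]]]
  keep <- !(is.na(g1) | is.na(g2))
  tab <- table(factor(g1[keep], levels = 0:2), factor(g2[keep], levels = 0:2))
  matrix(as.integer(tab), 3, 3, dimnames = list(0:2, 0:2))
}

# genotype-class probabilities for haplotype frequencies h = (h11,h10,h01,h00)
# cells in row-major (a, b) order, a = alt count locus 1, b = locus 2
two_locus_class_probs <- function(h) {
  h11 <- h[1]; h10 <- h[2]; h01 <- h[3]; h00 <- h[4]
  matrix(c(
    h00^2,           2 * h00 * h01,                 h01^2,
    2 * h00 * h10,   2 * (h11 * h00 + h10 * h01),   2 * h01 * h11,
    h10^2,           2 * h10 * h11,                 h11^2
  ), nrow = 3, byrow = TRUE, dimnames = list(0:2, 0:2))
}

two_locus_loglik <- function(h, tab) {
  p <- two_locus_class_probs(h)
  used <- tab > 0
  sum(tab[used] * log(pmax(p[used], .Machine$double.xmin)))
}

#' EM haplotype frequency estimation for two unphased biallelic loci
#'
#' Maximum-likelihood haplotype frequencies under random mating. The only
#' ambiguous genotype class is the double heterozygote, whose expected
#' cis/trans split is updated each iteration from the current frequencies
#' (posterior odds `h11 h00 / (h11 h00 + h10 h01)`). The observed allele
#' frequencies are preserved exactly at every iteration and the
#' log-likelihood is checked to be non-decreasing at every step.
#'
#' Three deterministic starts are run and the best likelihood kept:
#' linkage-equilibrium products of the observed allele frequencies, all
#' double heterozygotes phased cis, and all phased trans. The extra starts
#' matter because the equilibrium point always splits double heterozygotes
#' exactly 50/50 and is itself a stationary point for symmetric tables.
#'
#' @param tab 3x3 genotype count matrix as from [two_locus_table()].
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Iteration cap per start.
#' @return Object of class `haplotype_estimate`: list with `frequencies`
#'   (named `h11, h10, h01, h00`, "1" = alt allele), `log_likelihood`,
#'   `iterations` (of the winning start), `converged`.
#' @export
em_haplotypes <- function(tab, tol = 1e-10, max_iter = 1000) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(3, 3)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty genotype table", call. = FALSE)
  p1 <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)              # alt freq locus 1
  p2 <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    stop("degenerate locus (monomorphic): LD undefined", call. = FALSE)
  }
  ndh <- tab[2, 2]  # double heterozygotes
  # haplotype counts from unambiguous cells (excluding the double het cell)
  base <- c(
    h11 = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    h10 = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    h01 = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    h00 = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  )
  starts <- list(
    equilibrium = c(h11 = p1 * p2, h10 = p1 * (1 - p2),
                    h01 = (1 - p1) * p2, h00 = (1 - p1) * (1 - p2)),
    cis = (base + ndh * c(1, 0, 0, 1)) / (2 * n),
    trans = (base + ndh * c(0, 1, 1, 0)) / (2 * n)
  )
  best <- NULL
  for (h in starts) {
    ll <- two_locus_loglik(h, tab)
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      cis_num <- h[["h11"]] * h[["h00"]]
      trans_num <- h[["h10"]] * h[["h01"]]
      cis <- if (cis_num + trans_num > 0) cis_num / (cis_num + trans_num) else 0.5
      counts <- base + ndh * c(cis, 1 - cis, 1 - cis, cis)
      h_new <- stats::setNames(counts / (2 * n), names(h))
      ll_new <- two_locus_loglik(h_new, tab)
      if (ll_new < ll - 1e-9) {
        stop("EM log-likelihood decreased (", ll, " -> ", ll_new, ")",
             call. = FALSE)
      }
      delta <- ll_new - ll
      h <- h_new
      ll <- ll_new
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || ll > best$log_likelihood) {
      best <- list(frequencies = h, log_likelihood = ll,
                   iterations = iter, converged = converged)
    }
  }
  structure(best, class = "haplotype_estimate")
}

#' Pairwise linkage disequilibrium statistics from haplotype frequencies
#'
#' `D = h11 - p1 p2`; `D' = |D| / Dmax` with
#' `Dmax = min(p1 (1-p2), (1-p1) p2)` for positive D and
#' `min(p1 p2, (1-p1)(1-p2))` for negative D; `r^2 = D^2 / (p1 q1 p2 q2)`.
#'
#' @param h A `haplotype_estimate` or a named frequency vector
#'   `c(h11, h10, h01, h00)`.
#' @return List with `D`, `D_prime`, `r_squared`.
#' @examples
#' ld_stats(c(h11 = 0.5, h10 = 0, h01 = 0, h00 = 0.5))  # D' = 1, r2 = 1
#' @export
ld_stats <- function(h) {
  if (inherits(h, "haplotype_estimate")) h <- h$frequencies
  stopifnot(length(h) == 4, abs(sum(h) - 1) < 1e-6)
  p1 <- h[["h11"]] + h[["h10"]]
  p2 <- h[["h11"]] + h[["h01"]]
  if (min(p1, 1 - p1, p2, 1 - p2) <= 0) {
    stop("degenerate locus (fixed allele): LD undefined", call. = FALSE)
  }
  d <- h[["h11"]] - p1 * p2
  if (d == 0) {
    return(list(D = 0, D_prime = 0, r_squared = 0))
  }
  d_max <- if (d > 0) min(p1 * (1 - p2), (1 - p1) * p2)
           else min(p1 * p2, (1 - p1) * (1 - p2))
  list(D = d,
       D_prime = abs(d) / d_max,
       r_squared = d^2 / (p1 * (1 - p1) * p2 * (1 - p2)))
}

#' Find patients discordant with the two dominant haplotypes
#'
#' For a near-perfectly linked pair, the two dominant haplotypes compose only
#' three two-locus genotypes (the two double homozygotes and the double
#' heterozygote in the dominant phase). Patients whose genotype cannot be
#' built from those two haplotypes have "lost" the LD and are returned.
#'
#' @param cohort Cohort data frame.
#' @param pair Two variant column names, default the rs9923231/rs9934438 pair.
#' @param estimate Optional `haplotype_estimate`; computed from the cohort if
#'   missing. The two dominant haplotypes must jointly carry at least
#'   `min_dominant_mass` frequency, otherwise the notion is not applicable.
#' @param min_dominant_mass Default 0.99.
#' @return Character vector of discordant `patient_id`s (patients with a
#'   missing genotype at either locus are never flagged).
#' @export
find_ld_discordant <- function(cohort, pair = c("rs9923231", "rs9934438"),
                               estimate = NULL, min_dominant_mass = 0.99) {
  if (is.null(estimate)) {
    estimate <- em_haplotypes(two_locus_table(cohort, pair))
  }
  h <- estimate$frequencies
  ord <- order(h, decreasing = TRUE)
  if (h[ord[1]] + h[ord[2]] < min_dominant_mass) {
    stop("dominant haplotype pair carries < ", min_dominant_mass,
         " total frequency: discordance screen not applicable", call. = FALSE)
  }
  # alt-allele dosage of each haplotype at the two loci, order h11,h10,h01,h00
  alt1 <- c(1L, 1L, 0L, 0L)[ord[1:2]]
  alt2 <- c(1L, 0L, 1L, 0L)[ord[1:2]]
  valid <- unique(rbind(
    c(2L * alt1[1], 2L * alt2[1]),
    c(alt1[1] + alt1[2], alt2[1] + alt2[2]),
    c(2L * alt1[2], 2L * alt2[2])
  ))
  g1 <- cohort[[pair[1]]]
  g2 <- cohort[[pair[2]]]
  ok <- is.na(g1) | is.na(g2) |
    (paste(g1, g2) %in% paste(valid[, 1], valid[, 2]))
  cohort$patient_id[!ok]
}
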