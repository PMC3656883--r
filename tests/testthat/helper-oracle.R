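# Independent maximum-likelihood oracle for two-locus haplotype frequencies.
# Exploits the fact that the MLE preserves the observed allele margins, so the
# likelihood is a 1-D function of the cis-haplotype frequency h11; that
# frequency is found by dense grid search (no EM involved).
oracle_haplotypes <- function(tab, step = 1e-5) {
  n <- sum(tab)
  p1 <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)
  p2 <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  h11 <- seq(lo, hi, by = step)
  loglik <- function(h11) {
    h10 <- p1 - h11; h01 <- p2 - h11; h00 <- 1 - p1 - p2 + h11
    lg <- function(x) log(pmax(x, 1e-300))
    tab[1, 1] * lg(h00^2) + tab[1, 2] * lg(2 * h00 * h01) +
      tab[1, 3] * lg(h01^2) + tab[2, 1] * lg(2 * h00 * h10) +
      tab[2, 2] * lg(2 * (h11 * h00 + h10 * h01)) +
      tab[2, 3] * lg(2 * h01 * h11) + tab[3, 1] * lg(h10^2) +
      tab[3, 2] * lg(2 * h10 * h11) + tab[3, 3] * lg(h11^2)
  }
  coarse <- h11[which.max(loglik(h11))]
  fine <- seq(max(lo, coarse - step), min(hi, coarse + step), by = step / 100)
  best <- fine[which.max(loglik(fine))]
  c(h11 = best, h10 = p1 - best, h01 = p2 - best, h00 = 1 - p1 - p2 + best)
}

# EM must reproduce the oracle's frequencies; when the likelihood surface has
# tied global maxima (possible for symmetric tables, where the MLE is not
# unique) attaining the same maximum likelihood is the correct property.
expect_matches_oracle <- function(tab, tol = 2e-3, label = NULL) {
  est <- em_haplotypes(tab)
  o <- oracle_haplotypes(tab)
  freq_ok <- max(abs(est$frequencies - o)) <= tol
  ll_gap <- abs(est$log_likelihood - coumascreen:::two_locus_loglik(o, tab))
  testthat::expect_true(freq_ok || ll_gap < 1e-6, label = label)
}

# random 3x3 genotype table with both loci polymorphic
random_polymorphic_table <- function(max_total = 50) {
  repeat {
    probs <- stats::runif(9)
    tab <- matrix(stats::rmultinom(1, sample(4:max_total, 1), probs), 3, 3)
    p1 <- sum(tab * matrix(0:2, 3, 3)) / (2 * sum(tab))
    p2 <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * sum(tab))
    if (p1 > 0 && p1 < 1 && p2 > 0 && p2 < 1) return(tab)
  }
}
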