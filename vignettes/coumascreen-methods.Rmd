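---
title: "Methods: profile-based outlier screening for acenocoumarol dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profile-based outlier screening for acenocoumarol dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Coumarin anticoagulants (warfarin, acenocoumarol, phenprocoumon) have a
narrow therapeutic window and an inter-patient dose range of roughly an order
of magnitude. The two strongest genetic determinants are the VKORC1 promoter
SNP rs9923231 (-1639G>A), which reduces expression of the drug target, and
the CYP2C9 star alleles *2 and *3, which slow clearance. Combining the three
rs9923231 genotypes with the six CYP2C9 diplotypes yields 18 *genetic
profiles*, each with its own reference dose distribution. Patients whose
stable dose falls far outside their profile's reference range are candidates
for carrying *additional* rare variants — in VKORC1 in particular — and a
screen built on that idea (flag, exclude clinically explained cases, sequence
the rest) is what this package implements as a reusable, testable pipeline.

No individual-level data from the motivating study are available, so the
package ships a cohort simulator whose population quantities are calibrated
to that study's published summary tables (exposed verbatim by
`published_profile_table()`, `published_variant_table()`,
`published_discordant_patients()`, `published_stepwise_ladder()` and
`published_exclusion_counts()`). Every downstream stage — IO, profiling,
screening, LD analysis, association tests, stepwise regression — is exercised
end-to-end against cohorts whose true structure is known by construction.

## The simulated cohort

`simulate_cohort()` draws, for `n_patients` (default 3949, the reference
cohort size):

* **rs9923231/rs9934438** as two haplotypes from the four-haplotype
  distribution (G-C, G-T, A-C, A-T). The default frequencies
  (0.5913, 0.00038, 0.00038, 0.4080) are chromosome counts from the joint
  genotype table reconstructed from the published per-profile counts plus the
  six published recombinant ("LD-lost") patients, with double heterozygotes
  phased to the dominant G-C/A-T configuration (for this table the EM
  estimate is identical to five decimal places). The implied recombinant mass
  reproduces about six discordant individuals per 3949 and a pairwise
  r² of ~0.997.
* **rs17878544/rs7200749** from a haplotype table built by
  `haplotype_freqs_from_ld()` with the published minor allele frequencies
  (0.0217, 0.0115) and D' = 0.99. A note on consistency: with these allele
  frequencies, D' = 0.99 pins r² at 0.514; the value 0.53 sometimes quoted
  for this pair is not attainable jointly with D' = 0.99 (it would require
  D' > 1). We treat D' as the binding constraint and let r² follow.
* **CYP2C9** as two alleles from (*1, *2, *3) frequencies (0.765, 0.165,
  0.070, derived from the published diplotype counts); the analysis encodes
  the diplotype as the ordinal score *s* = (#*2 alleles) + 2(#*3 alleles).
  The source tables never state a coding; this one reproduces the monotone
  dose ranking across profiles and keeps the model additive with one degree
  of freedom.
* **Rare variants** (D36Y, L128R) as independent heterozygous-carrier
  Bernoullis (14/3949 and 1/3949); rs55894764 as a binomial in its MAF
  (0.0261, i.e. carrier frequency ~5.1%).
* **Demographics**: age ~ N(74, 10²) truncated at the eligibility bound of
  18 years; BMI ~ N(29.5, 7.4²) truncated at 15; 49% male; 10% titrated to
  the higher 2.5-3.5 INR target.
* **Clinical-condition flags** as independent Bernoullis at the published
  per-category exclusion counts divided by the cohort size (eight clinical
  categories plus a no-clinical-data marker).

Two optional overrides (`vkorc1_genotype_freqs`, `cyp2c9_diplotype_freqs`)
draw genotypes from marginal frequencies directly instead of from random
allele/haplotype pairing. They exist because observed cohort counts deviate
slightly from Hardy-Weinberg proportions; when the goal is to match published
*genotype* marginals exactly in expectation, drawing from them is the honest
emulation.

All randomness flows through one seed (`withr::with_seed`), so a fixed seed
gives a byte-identical cohort. The default seed is 17.

## The dose model and its calibration

The weekly dose is additive:

dose = b0 + b_vk·gA + b_age·(age - 74) + b_cyp·s + b_d36y·I(D36Y) +
b_r12r·I(R12R) + shift_clinical + e,  e ~ N(0, sigma²),

truncated below at 1 mg/week (truncation rather than resampling; the affected
mass is negligible except in the rarest fully-variant profiles, which the
screen skips anyway). The intercept 18 mg/week is the wild-type (GG, *1*1)
profile reference dose; rs9923231 is coded additively as the A-allele count
because the published GG > GA > AA dose gradient is close to linear.

`calibrate_effects()` turns *variance fractions* into effect sizes. With
mutually independent predictors (which the simulator guarantees),
the fraction of dose variance explained by predictor *j* is
f_j = beta_j² Var(x_j) / Var(dose), so

beta_j = ± sqrt(f_j · V / Var(x_j)),   sigma = sqrt((1 - sum f_j) · V),

with V = 36 mg²/week² (whole-sample dose 14 ± 6). Signs follow the
pharmacology: A alleles, age and impaired CYP2C9 lower the dose, rare
variants raise it.

The default fractions come from the published stepwise summary. That summary
is internally inconsistent in a way any re-implementation must confront: its
cumulative-R² column gives increments (0.210, 0.130, 0.051, 0.004, 0.005) —
ranking rs55894764 *above* D36Y in marginal contribution — while its
final-model standardized coefficients (-0.461, -0.364, -0.216, 0.061, 0.034)
and the printed p value for rs55894764 (0.006, i.e. |t| ≈ 2.75, incompatible
with an increment of 0.005 at n = 3949) rank D36Y above rs55894764, which is
also the published entry order. Under predictor independence no simulator can
satisfy both columns. Our resolution: keep the first three increments as
printed, keep the total late contribution 0.009 (0.391 → 0.400), and split it
between D36Y and rs55894764 in the ratio of the squared standardized
coefficients (0.061² : 0.034²), giving fractions ≈ 0.0069 and 0.0021. This
preserves the ladder endpoints and reproduces the published entry order;
it was fixed at design time and is not a tuning knob.

Clinical-condition flags add a mean-zero dose shift of ±Uniform(6, 12)
mg/week, so that flagged patients plausibly become outliers (the source
reports no effect sizes for these conditions; the range is a config knob).
The analytic variance of that shift is subtracted from the residual so the
*marginal* dose variance stays at V and the R² calibration is not diluted.
Sex and BMI are simulated but carry no dose effect by default — the reference
analysis reports age as the only demographic that entered — though both are
configurable and are offered to the stepwise selector by default.

## Profiling and screening

`assign_profile()` maps (rs9923231 genotype, CYP2C9 diplotype) to ids 1-18 in
the canonical order: diplotypes (*1*1, *1*2, *1*3, *2*2, *2*3, *3*3) crossed
with (GG, GA, AA). The source table's numbering skips one id and repeats
another in its tail; we renumber consistently with its accompanying text
(the fully variant AA + *3*3 profile is #18).

`reference_dose_table()` reports per-profile n, mean, SD (n-1 denominator;
the estimator is not stated in the source) and prevalence.
`flag_outliers()` flags |dose - mean| > 2·SD *strictly* — "outside" treats a
boundary dose as inside. The reference statistics are computed once on the
full cohort including prospective outliers (the described procedure is
one-pass; no leave-one-out and no re-screening after exclusions). Profiles
with fewer than `min_n = 10` patients are reported but skipped by the screen:
their SD estimate is too unstable to define a meaningful 2SD band. The
threshold is a knob; the source is silent on the issue.

`apply_exclusions()` removes flagged patients with any clinical-condition
flag or no clinical data. A patient with several flags is excluded once,
attributed to the first matching category in the canonical order — the
source reports disjoint per-category counts without stating a rule, and
first-match attribution makes the tallies well defined and conserved
(flagged = retained + excluded, which the tests assert).

Under a purely Gaussian within-profile dose model the expected flagged
fraction is 2·Phi(-2) ≈ 4.55%, and the test suite checks this on a
confounder-free cohort of 20,000. The empirical 3.7% of the reference cohort
is data-specific (its dose distribution is not exactly Gaussian within
profiles) and is deliberately not asserted.

## Two-locus haplotype estimation and LD

`em_haplotypes()` is the classical gene-counting EM for two unphased
biallelic loci: the double heterozygote is the only ambiguous class, split
each iteration by the posterior cis odds h11·h00 / (h11·h00 + h10·h01).
Observed allele frequencies are preserved exactly at every iteration, the
log-likelihood is asserted non-decreasing, and iteration stops when the
increase drops below 1e-10 (cap 1000).

One numerical subtlety: at the linkage-equilibrium start the cis odds are
*always* exactly 1/2 (h11·h00 = h10·h01 there), so for symmetric tables the
equilibrium point is a stationary saddle the EM never leaves. Property
testing against an independent grid-search likelihood oracle surfaced this
(a 5-individual counterexample lives in the test suite), so the estimator
runs three deterministic starts — equilibrium, all double heterozygotes cis,
all trans — and keeps the best likelihood. It remains fully deterministic.
A second subtlety: for some symmetric tables the likelihood has two mirrored
global maxima (the sign of D is unidentifiable); the oracle-equivalence test
therefore accepts either matching frequencies or an exactly matching maximum
likelihood.

`ld_stats()` computes D = h11 - p1·p2, D' = |D|/Dmax (reported as an
absolute value) and r² = D²/(p1·q1·p2·q2). `find_ld_discordant()` flags
patients whose two-locus genotype cannot be composed from the two dominant
haplotypes; it requires those haplotypes to jointly carry ≥ 99% frequency,
since "losing the LD" is only meaningful against near-perfect linkage.
`inject_ld_discordant()` plants the six published recombinant genotype
patterns for round-trip testing.

## Association tests and the stepwise model

Carrier comparisons use the dominant model (het + hom), matching how the
reference tables group genotypes, with Welch's t test as the default:
the carrier groups are tiny (as few as 14 against ~3900) and assuming equal
variances across such imbalance is not defensible. The pooled-variance
variant is provided because the source does not state which was used; for its
D36Y summaries the Welch p is 0.0055 and neither variant reproduces the
printed 0.004 from the rounded summaries, so the printed value is documented
but not asserted. `t_test_from_summaries()` works from (n, mean, SD)
directly — a form base R's `t.test()` does not accept — and is
property-tested to agree with `t.test()` on raw data to 1e-9.

`stepwise_fit()` is full stepwise selection (forward entry by smallest
partial-F p < 0.05, backward removal at p > 0.10 after each entry — the
defaults of the commercial statistics package named by the reference
analysis; the exact stepwise variant used there is unstated). The response
stays on the raw mg/week scale (no transform is indicated anywhere).
Reported coefficients are standardized betas from a z-scored refit of the
final model: the published coefficient magnitudes (|beta| < 1 against a dose
range of ~5-40 mg/week) are only consistent with standardization. The
published sign of the D36Y coefficient is inconsistent between that table
(-0.061) and its accompanying text (0.061); this package reports the sign
its own fit produces, which is positive (carriers need more drug).
Collinear or constant candidates are skipped with a warning rather than
allowed to destabilize the fit.

## Problem sizes and tolerances in the checks

The test suite simulates at n = 100,000 for frequency-convergence and
single-predictor R² checks (±0.02 on fractions), n = 3949 × 10 seeds for
ladder and coefficient recovery (±0.03 on R², matching the granularity at
which cumulative R² is published), n = 20,000 for the Gaussian screening
null, 1000 replicates for the type-I error of the carrier test and 200 for
its power, and 200 random small tables for EM/oracle equivalence (2e-3).
These sizes were chosen so each stochastic check has comfortable margin over
its binomial/sampling noise while the whole suite stays quick.

## What the simulator does not emulate

Known limitations, which bound what a passing suite says about real cohorts:

* No population stratification, no genotyping error, no pedigree structure,
  and no Hardy-Weinberg departures unless marginal-frequency overrides are
  used.
* Dose is a one-shot linear draw; real steady doses come from INR-guided
  titration over time, with measurement error and clinical feedback.
* Clinical confounders are independent coin flips with a symmetric dose
  shift; in reality they correlate with age, with each other, and push doses
  asymmetrically.
* Within-profile dose distributions are Gaussian by construction; real ones
  are right-skewed, which is why the reference cohort's empirical flagged
  fraction (3.7%) sits below the Gaussian 4.55%.
* The two CYP2C9 sites are treated as statistically independent of VKORC1
  (different chromosomes — safe) and of each other only through multinomial
  allele draws (no phasing within CYP2C9 is attempted).
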