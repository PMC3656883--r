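# coumascreen

Pharmacogenetic outlier screening for coumarin anticoagulant dosing.

Stable weekly doses of acenocoumarol vary roughly tenfold between patients.
Most of the explainable variance sits in two genes: the drug target *VKORC1*
(promoter SNP rs9923231, −1639G>A) and the metabolizing enzyme *CYP2C9*
(star alleles \*2 and \*3). Crossing the three rs9923231 genotypes with the
six CYP2C9 diplotypes defines 18 **genetic profiles**, each with a reference
dose distribution. A patient whose stable dose lies strictly outside the
profile's mean ± 2SD band is an **outlier** — and, once patients with a
clinical explanation (liver failure, interacting drugs, …) are excluded, the
remainder are prime candidates for carrying additional rare *VKORC1*
variants (D36Y, L128R, rs55894764, rs7200749, rs17878544, or loss of the
rs9923231/rs9934438 linkage).

`coumascreen` implements that discovery strategy as a tested pipeline for
statistical geneticists and pharmacogenetics groups:

* **Profiling / screening** — per-profile reference dose tables
  (mean, SD, prevalence), strict mean ± 2SD outlier flagging, and the
  clinical exclusion cascade with disjoint per-category tallies.
* **Population genetics** — two-locus EM haplotype frequency estimation from
  unphased genotypes (gene-counting EM with deterministic multi-start),
  D / D′ / r² linkage disequilibrium statistics, and detection of patients
  discordant with the dominant haplotype pair of a near-perfectly linked SNP
  pair.
* **Association** — carrier vs non-carrier Welch/pooled t tests, computable
  directly from published-style (n, mean, SD) summaries, and Pearson
  correlation.
* **Dose modelling** — full stepwise additive linear regression of weekly
  dose (entry p < 0.05, removal p > 0.10) reporting the cumulative R² ladder
  and standardized coefficients.
* **Synthetic cohorts** — a simulator whose defaults are calibrated to the
  published summary tables of a 3949-patient acenocoumarol cohort
  (`published_profile_table()` and friends), with genotype structure,
  LD structure, rare-variant carrier rates, clinical confounders and an
  additive dose model whose per-predictor variance fractions are set by
  `calibrate_effects()`: βⱼ = ±√(fⱼ·V / Var(xⱼ)).
* **IO** — VCF 4.2 (unphased diploid GT) and a fixed-schema phenotype TSV,
  with strict validation and exact write→read round trips.

## Worked example

```r
library(coumascreen)

cfg <- default_cohort_config()        # n = 3949, seed 17, calibrated defaults
cohort <- simulate_cohort(cfg)

# 1. per-profile reference doses
ref <- reference_dose_table(cohort)
head(ref[ref$n > 0, 1:7], 4)
#>   profile_id cyp2c9 vkorc1    n mean_dose sd_dose prevalence
#> 1          1   *1*1     GG  779     18.39    5.16     0.1973
#> 2          2   *1*1     GA 1157     14.08    5.17     0.2930
#> 3          3   *1*1     AA  379      9.93    4.73     0.0960
#> 4          4   *1*2     GG  365     16.98    5.27     0.0924

# 2. outlier screen + clinical exclusion cascade
res <- apply_exclusions(flag_outliers(cohort, ref), cohort)
#> apply_exclusions: 171 flagged = 139 retained + 32 excluded

# 3. LD of the near-perfect promoter/intron pair, and who breaks it
est <- em_haplotypes(two_locus_table(cohort, c("rs9923231", "rs9934438")))
unlist(ld_stats(est))
#>        D  D_prime r_squared
#>    0.242    0.999     0.998
find_ld_discordant(cohort, estimate = est)
#> [1] "P00827" "P01013" "P01456"

# 4. does the rare missense variant shift the dose?
carrier_association(cohort, "D36Y")[c("n_carrier", "mean_carrier",
                                      "mean_noncarrier", "p_value")]
#>   n_carrier mean_carrier mean_noncarrier p_value
#> 1        17         19.7            13.9   0.002

# 5. stepwise dose model: the cumulative R-squared ladder
r2_ladder(stepwise_fit(cohort))
#>    predictor r_squared      p            beta
#> 1  rs9923231     0.235 <0.001 -0.479 (<0.001)
#> 2        age     0.362 <0.001 -0.361 (<0.001)
#> 3     cyp2c9     0.410 <0.001 -0.220 (<0.001)
#> 4       D36Y     0.416 <0.001  0.078 (<0.001)
#> 5 rs55894764     0.421 <0.001  0.066 (<0.001)
```

Reading the output: the wild-type profile (GG, \*1\*1) needs ~18 mg/week
while the fully common-variant profiles need half that; ~4% of patients fall
outside their profile's 2SD band; the promoter/intron pair is in near-perfect
LD (r² ≈ 0.998) with a handful of recombinant patients; D36Y carriers need
~6 mg/week more than non-carriers; and the five-predictor additive model
explains ~42% of dose variance on this replicate, entered in the canonical
order with rs9923231 dominating.

`run_pipeline(cfg, out_dir)` chains all stages, writes
`cohort.vcf`, `pheno.tsv`, `profiles.tsv`, `calls.tsv`, `ld.json`,
`assoc.tsv`, `ladder.tsv` and a markdown report, and is byte-reproducible
per seed. A thin command-line front end with the same stages lives at
`inst/cli/coumascreen.R`:

```sh
Rscript inst/cli/coumascreen.R run --seed 17 --out-dir out/
Rscript inst/cli/coumascreen.R ld --vcf out/cohort.vcf --pheno out/pheno.tsv \
        --pair rs9923231,rs9934438 --out ld.json
```

## Method details

The methods vignette (`vignettes/coumascreen-methods.Rmd`) documents the
dose-model calibration (including how the internally inconsistent published
stepwise summary was reconciled), the EM multi-start rationale, screening
conventions (strict 2SD boundary, one-pass reference statistics, minimum
profile size), the exclusion attribution rule, and what the simulator does
and does not emulate about real anticoagulation cohorts.
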