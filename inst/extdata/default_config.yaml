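# Default cohort configuration, calibrated to the published summary tables of
# a 3949-patient acenocoumarol cohort (see ?published_profile_table):
# - main-pair haplotype frequencies: chromosome counts from the joint
#   rs9923231/rs9934438 genotype reconstruction (profile-table marginals plus
#   the six published discordant patients)
# - CYP2C9 allele frequencies: diplotype counts of the profile table
# - rare-variant frequencies: published whole-sample genotype counts
# - dose model: intercept 18 mg/week = wild-type profile reference dose;
#   effects from calibrate_effects() with total variance 36 mg^2/week^2 and
#   variance fractions from the published stepwise ladder (see the methods
#   vignette for the D36Y/R12R split); residual_sd has the clinical-confounder
#   shift variance already removed
# - confounder rates: published exclusion tally / 3949
# Regenerate with: write_cohort_config(default_cohort_config(), <path>)
n_patients: 3949
seed: 17
haplotype_freqs_main_pair:
  G-C: 0.591288933907318
  G-T: 0.000379842998227
  A-C: 0.000379842998227
  A-T: 0.407951380096227
ld_pair_secondary:
  maf_rs17878544: 0.021656534954407
  maf_rs7200749: 0.011521904279564
  d_prime: 0.99
maf_r12r: 0.026102382159149
carrier_freq_d36y: 0.003545201316789
carrier_freq_l128r: 0.000253228665485
cyp2c9_allele_freqs:
  '*1': 0.76487718409724
  '*2': 0.165105089896176
  '*3': 0.070017726006584
age_mean_sd:
- 74.0
- 10.0
bmi_mean_sd:
- 29.5
- 7.4
sex_ratio: 0.49
inr_high_target_prop: 0.1
dose_model:
  intercept: 18.0
  effects:
    rs9923231: -3.95548989457223
    age: -0.216333076527839
    cyp2c9: -1.614766623278086
    D36Y: 8.365207340285812
    rs55894764: 1.253601079515594
    rs7200749: 0.0
    rs17878544: 0.0
    L128R: 0.0
    sex: 0.0
    bmi: 0.0
  residual_sd: 4.452807234754872
  age_center: 74.0
  target_variance_fractions:
    rs9923231: 0.21
    age: 0.13
    cyp2c9: 0.051
    D36Y: 0.006866721345089
    rs55894764: 0.002133278654911
confounder_rates:
  autoimmune_disease: 0.002532286654849
  liver_failure: 0.00151937199291
  severe_heart_failure: 0.002025829323879
  severe_copd: 0.002532286654849
  interacting_drugs: 0.009369460622943
  new_thrombotic_event: 0.00151937199291
  obesity: 0.00050645733097
  tumoral_disease: 0.001266143327425
  no_clinical_data: 0.00101291466194
confounder_shift_range:
- 6.0
- 12.0
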