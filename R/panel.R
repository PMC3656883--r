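#' Variant panel used by the pipeline
#'
#' Definitions of the nine biallelic sites the pipeline genotypes: seven in
#' VKORC1 (promoter, intron 1 and coding region) and the two CYP2C9
#' star-allele sites. Positions are synthetic but ascending within each
#' chromosome, which is all the VCF writer needs.
#'
#' @return A data frame with one row per site: `variant_id`, `gene`,
#'   `gene_region`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `notes`.
#' @export
variant_panel <- function() {
  panel <- data.frame(
    variant_id = c("rs9923231", "rs17878544", "rs9934438", "rs55894764",
                   "D36Y", "rs7200749", "L128R", "rs1799853", "rs1057910"),
    gene = c(rep("VKORC1", 7), "CYP2C9", "CYP2C9"),
    gene_region = c("promoter", "promoter", "intron", "coding",
                    "coding", "coding", "coding", "coding", "coding"),
    chrom = c(rep("chr16", 7), "chr10", "chr10"),
    pos = c(31096368L, 31096657L, 31102321L, 31104878L,
            31104950L, 31105554L, 31105578L, 94942290L, 94981296L),
    ref_allele = c("G", "A", "C", "G", "G", "C", "T", "C", "A"),
    alt_allele = c("A", "G", "T", "A", "T", "T", "G", "T", "C"),
    notes = c("-1639G>A, main promoter dose determinant", "g.3350A>G",
              "1173C>T, near-perfect LD with rs9923231", "R12R synonymous",
              "D36Y coumarin-resistance missense", "L120L synonymous",
              "L128R coumarin-resistance missense",
              "CYP2C9*2", "CYP2C9*3"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(panel$variant_id), all(panel$ref_allele != panel$alt_allele))
  panel
}

#' Canonical clinical exclusion categories
#'
#' The eight clinical conditions that can explain an unexpected dose
#' requirement, plus the marker for patients with no retrievable clinical
#' data. Order matters: [apply_exclusions()] attributes a multi-flag patient
#' to the first matching category.
#'
#' @return Character vector of the nine category labels.
#' @export
clinical_flag_levels <- function() {
  c("autoimmune_disease", "liver_failure", "severe_heart_failure",
    "severe_copd", "interacting_drugs", "new_thrombotic_event",
    "obesity", "tumoral_disease", "no_clinical_data")
}

#' CYP2C9 diplotype labels in canonical order
#' @return Character vector of the six diplotypes.
#' @export
cyp2c9_diplotypes <- function() c("*1*1", "*1*2", "*1*3", "*2*2", "*2*3", "*3*3")

#' VKORC1 rs9923231 genotype labels in canonical order
#' @return Character vector `c("GG", "GA", "AA")`.
#' @export
vkorc1_genotypes <- function() c("GG", "GA", "AA")
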