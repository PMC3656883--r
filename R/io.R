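#' Write a cohort's genotypes as VCF 4.2
#'
#' One record per panel site, unphased diploid GT, samples in cohort order.
#' Positions and chromosomes come from [variant_panel()].
#'
#' @param cohort Cohort data frame with one alt-allele-count column per panel
#'   variant (NA for missing genotypes).
#' @param path Output file path (plain-text `.vcf`).
#' @param panel Variant definition table, default [variant_panel()].
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, panel = variant_panel()) {
  missing_cols <- setdiff(panel$variant_id, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks genotype column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=coumascreen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$patient_id), collapse = "\t")
  )
  ord <- order(panel$chrom, panel$pos)
  records <- vapply(ord, function(i) {
    counts <- cohort[[panel$variant_id[i]]]
    gt <- ifelse(is.na(counts), "./.", gt_code[counts + 1L])
    paste(c(panel$chrom[i], panel$pos[i], panel$variant_id[i],
            panel$ref_allele[i], panel$alt_allele[i], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read unphased diploid genotypes from a VCF
#'
#' Parses with `vcfR` and converts each diploid GT to an alt-allele count;
#' `./.` becomes NA. Sample order is preserved.
#'
#' @param vcf_path Path to a VCF file with a GT FORMAT field.
#' @return Data frame with `patient_id` plus one integer column per variant
#'   (named by the VCF ID column).
#' @export
read_genotypes <- function(vcf_path) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path, call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  if (anyNA(ids) || anyDuplicated(ids)) {
    stop("VCF records must carry unique IDs", call. = FALSE)
  }
  rownames(gt) <- ids
  ok <- is.na(gt) | grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("non-diploid GT '", gt[!ok][1], "' at record ", ids[bad[1]],
         call. = FALSE)
  }
  multi <- grepl("[2-9]", gt)
  if (any(multi)) {
    stop("multi-allelic GT not supported (record ",
         ids[which(rowSums(multi) > 0)[1]], ")", call. = FALSE)
  }
  counts <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                   dimnames = list(NULL, rownames(gt)))
  for (v in rownames(gt)) {
    g <- gt[v, ]
    known <- !is.na(g) & !grepl("\\.", g)
    cnt <- rep(NA_integer_, length(g))
    cnt[known] <- vapply(strsplit(g[known], "[/|]"),
                         function(a) sum(a == "1"), integer(1))
    counts[, v] <- cnt
  }
  message("read_genotypes: ", nrow(counts), " samples x ", ncol(counts),
          " variants from ", vcf_path)
  data.frame(patient_id = colnames(gt), counts,
             check.names = FALSE, stringsAsFactors = FALSE)
}

pheno_columns <- function() {
  c("patient_id", "age", "sex", "bmi", "weekly_dose_mg", "inr_target",
    "clinical_flags")
}

#' Write the phenotype/clinical table as TSV
#'
#' Fixed header: `patient_id, age, sex, bmi, weekly_dose_mg, inr_target,
#' clinical_flags` (flags semicolon-joined, empty string when none).
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  out <- data.frame(
    patient_id = cohort$patient_id, age = cohort$age, sex = cohort$sex,
    bmi = cohort$bmi, weekly_dose_mg = cohort$weekly_dose,
    inr_target = cohort$inr_target, clinical_flags = cohort$clinical_flags,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate the phenotype/clinical table
#'
#' @param tsv_path Path to a TSV written by [write_phenotypes()] (or
#'   hand-built to the same schema).
#' @return Data frame of patient records (genotypes unset) with the internal
#'   column name `weekly_dose`.
#' @export
read_phenotypes <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("no such file: ", tsv_path, call. = FALSE)
  ph <- utils::read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = NULL,
                          colClasses = c(patient_id = "character",
                                         clinical_flags = "character"))
  missing_cols <- setdiff(pheno_columns(), names(ph))
  if (length(missing_cols)) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(ph$weekly_dose_mg)) || any(ph$weekly_dose_mg <= 0)) {
    stop("weekly_dose_mg must be positive for every patient", call. = FALSE)
  }
  if (any(ph$age < 18)) {
    stop("patients must be aged 18 or over (eligibility)", call. = FALSE)
  }
  if (!all(ph$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  flags <- parse_clinical_flags(ph$clinical_flags)
  unknown <- setdiff(unique(unlist(flags)), clinical_flag_levels())
  if (length(unknown)) {
    stop("unknown clinical flag label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  names(ph)[names(ph) == "weekly_dose_mg"] <- "weekly_dose"
  message("read_phenotypes: ", nrow(ph), " patients from ", tsv_path)
  ph
}

#' Split semicolon-joined clinical flags into label sets
#' @param x Character vector of semicolon-joined labels ("" = none).
#' @return List of character vectors.
#' @export
parse_clinical_flags <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Assemble a cohort from genotype and phenotype tables
#'
#' Joins [read_genotypes()] and [read_phenotypes()] output by `patient_id`.
#' Any patient present in one table but not the other is a hard error: the
#' screening denominators must be exact, so no silent intersection.
#'
#' @param genotypes Data frame from [read_genotypes()].
#' @param phenotypes Data frame from [read_phenotypes()].
#' @return Cohort data frame in phenotype order.
#' @export
assemble_cohort <- function(genotypes, phenotypes) {
  only_g <- setdiff(genotypes$patient_id, phenotypes$patient_id)
  only_p <- setdiff(phenotypes$patient_id, genotypes$patient_id)
  if (length(only_g) || length(only_p)) {
    stop("patient sets differ between VCF and phenotype table (",
         length(only_g), " only in VCF, ", length(only_p),
         " only in phenotypes)", call. = FALSE)
  }
  idx <- match(phenotypes$patient_id, genotypes$patient_id)
  cbind(phenotypes, genotypes[idx, setdiff(names(genotypes), "patient_id"),
                              drop = FALSE])
}

#' Read a cohort from a VCF + phenotype TSV pair
#' @param vcf_path,tsv_path File paths.
#' @return Cohort data frame.
#' @export
read_cohort <- function(vcf_path, tsv_path) {
  assemble_cohort(read_genotypes(vcf_path), read_phenotypes(tsv_path))
}
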