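#' Construct a cohort genotype container
#'
#' Holds risk-allele dosages for a cohort: a subjects x variants integer
#' matrix in \{0,1,2\} plus a logical missingness mask of the same shape.
#' Dosage values are only meaningful where the mask is \code{FALSE}.
#'
#' @param subject_ids Character vector of subject identifiers (rows).
#' @param dosage Integer matrix, subjects in rows, panel variants in columns
#'   (column names are variant ids).
#' @param missing_mask Logical matrix, same shape as \code{dosage}.
#' @return An object of class \code{cohort_genotypes}.
#' @export
cohort_genotypes <- function(subject_ids, dosage, missing_mask) {
  dosage <- as.matrix(dosage)
  missing_mask <- as.matrix(missing_mask)
  if (!all(dim(dosage) == dim(missing_mask))) {
    stop("dosage and missing_mask dimensions differ")
  }
  if (length(subject_ids) != nrow(dosage)) {
    stop("subject_ids length does not match dosage rows")
  }
  ok <- missing_mask | (dosage %in% 0:2 & !is.na(dosage))
  if (!all(ok)) stop("non-missing dosages must be integers in 0..2")
  rownames(dosage) <- subject_ids
  rownames(missing_mask) <- subject_ids
  structure(list(subject_ids = as.character(subject_ids),
                 dosage = dosage,
                 missing_mask = missing_mask),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", nrow(x$dosage), "subjects x",
      ncol(x$dosage), "variants;",
      sum(x$missing_mask), "missing calls\n")
  invisible(x)
}

# complement of a single base
.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Extract panel risk-allele dosages from a VCF
#'
#' Locates each panel variant in a VCF by chromosome and position and counts
#' risk alleles per diploid genotype. Allele matching is attempted on
#' REF/ALT as given, then with risk/other swapped. Weight-table alleles are
#' taken as positive strand: if a variant only matches after base
#' complementation this is treated as a strand inconsistency and raises an
#' error rather than silently flipping. Panel variants absent from the VCF
#' or with mismatched alleles are marked missing for all subjects;
#' non-diploid or uncalled genotypes are marked missing per call with a
#' warning.
#'
#' @param vcf_path Path to a VCF 4.x file (plain text or bgzipped).
#' @param weights A [snp_weight_table][load_weight_table] describing the panel.
#' @return A [cohort_genotypes] object with one column per panel variant,
#'   in panel order.
#' @export
dosages_from_vcf <- function(vcf_path, weights) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  subjects <- colnames(gt_raw)
  if (is.null(subjects) || length(subjects) == 0L) stop("VCF has no sample columns")

  n_sub <- length(subjects)
  n_var <- nrow(weights)
  dosage <- matrix(NA_integer_, n_sub, n_var,
                   dimnames = list(subjects, weights$variant_id))
  missing <- matrix(TRUE, n_sub, n_var,
                    dimnames = list(subjects, weights$variant_id))
  found_any <- FALSE
  n_bad_ploidy <- 0L

  vcf_chrom <- as.character(fix[, "CHROM"])
  vcf_pos <- as.integer(fix[, "POS"])

  for (i in seq_len(n_var)) {
    hit <- which(vcf_chrom == weights$chrom[i] & vcf_pos == weights$pos[i])
    if (length(hit) == 0L) next
    hit <- hit[1L]
    ref <- toupper(fix[hit, "REF"])
    alt <- toupper(fix[hit, "ALT"])
    if (is.na(alt) || alt == ".") alt <- ""
    risk <- weights$risk_allele[i]
    other <- weights$other_allele[i]

    # risk_is_alt: count of ALT alleles is the dosage; risk_is_ref: 2 - count
    if (ref == other && (alt == risk || alt == "")) {
      risk_is_alt <- TRUE
    } else if (ref == risk && (alt == other || alt == "")) {
      risk_is_alt <- FALSE
    } else {
      comp_pair <- c(.complement[[risk]], .complement[[other]])
      if (ref %in% comp_pair && (alt == "" || alt %in% comp_pair)) {
        stop("strand inconsistency for ", weights$variant_id[i],
             ": VCF alleles ", ref, "/", alt,
             " match the panel alleles only after complementation; ",
             "panel alleles are positive strand and are never flipped")
      }
      next  # allele mismatch: leave missing
    }
    found_any <- TRUE

    calls <- gt_raw[hit, , drop = TRUE]
    alleles <- strsplit(as.character(calls), "[/|]")
    for (j in seq_len(n_sub)) {
      a <- alleles[[j]]
      if (length(a) != 2L || any(is.na(a)) || any(a == ".")) {
        if (!is.na(calls[j]) && length(a) != 2L) n_bad_ploidy <- n_bad_ploidy + 1L
        next
      }
      n_alt <- sum(a != "0")
      dosage[j, i] <- if (risk_is_alt) n_alt else 2L - n_alt
      missing[j, i] <- FALSE
    }
  }

  if (!found_any) {
    stop("no panel variant could be located in ", vcf_path,
         " (matching is by chrom+pos with allele agreement)")
  }
  if (n_bad_ploidy > 0L) {
    warning(n_bad_ploidy, " genotype call(s) with ploidy != 2 set to missing")
  }
  cohort_genotypes(subjects, dosage, missing)
}
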