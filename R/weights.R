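#' Load a SNP weight table for the Type 1 diabetes genetic risk score
#'
#' Reads a tab-separated weight table defining an additive genetic risk
#' score: one row per variant with its risk (effect) allele, the other
#' allele and the per-allele weight on the ln(odds ratio) scale. Alleles
#' are taken to be reported on the positive strand; no strand flipping is
#' ever applied downstream.
#'
#' @param path Path to a TSV file with a header. Required columns:
#'   \code{variant_id}, \code{chrom}, \code{pos} (1-based), \code{risk_allele},
#'   \code{other_allele} and a weight column. The weight column may be named
#'   \code{weight} or any alias in \code{weight_aliases}. Extra columns are
#'   kept but ignored by the score computation.
#' @param weight_aliases Character vector of accepted header names for the
#'   weight column, tried in order.
#' @return A \code{data.frame} of class \code{snp_weight_table} with the
#'   canonical column names, one row per panel variant.
#' @seealso [grs9_panel()] for the bundled synthetic nine-SNP panel,
#'   [compute_grs()] for scoring.
#' @export
load_weight_table <- function(path,
                              weight_aliases = c("weight", "ln_or", "lnor", "log_or", "beta")) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) < 1L) stop("weight table is empty: ", path)

  wcol <- intersect(weight_aliases, names(tab))
  if (length(wcol) == 0L) {
    stop("no weight column found; expected one of: ",
         paste(weight_aliases, collapse = ", "))
  }
  names(tab)[names(tab) == wcol[1L]] <- "weight"

  required <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele", "weight")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("weight table missing column(s): ", paste(missing_cols, collapse = ", "))
  }

  # coerce with per-line error reporting (header is line 1)
  pos_num <- suppressWarnings(as.numeric(tab$pos))
  w_num <- suppressWarnings(as.numeric(tab$weight))
  bad <- which(is.na(pos_num) | is.na(w_num))
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1L] + 1L,
         " of ", path, ": non-numeric pos or weight")
  }
  tab$pos <- as.integer(pos_num)
  tab$weight <- w_num
  tab$chrom <- as.character(tab$chrom)
  tab$variant_id <- as.character(tab$variant_id)
  tab$risk_allele <- toupper(as.character(tab$risk_allele))
  tab$other_allele <- toupper(as.character(tab$other_allele))

  validate_weight_table(tab)
  class(tab) <- c("snp_weight_table", "data.frame")
  tab
}

#' Validate a SNP weight table
#'
#' Checks the invariants a weight table must satisfy: unique variant ids,
#' finite strictly positive weights (risk-increasing orientation), single-base
#' alleles that differ, and positive 1-based positions.
#'
#' @param tab A data.frame with the canonical weight-table columns.
#' @return The table, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_weight_table <- function(tab) {
  dup <- tab$variant_id[duplicated(tab$variant_id)]
  if (length(dup) > 0L) {
    stop("duplicated variant_id in weight table: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(tab$weight))) stop("non-finite weight in weight table")
  if (any(tab$weight <= 0)) {
    stop("non-positive weight for: ",
         paste(tab$variant_id[tab$weight <= 0], collapse = ", "),
         " (weights must be oriented to the risk-increasing allele)")
  }
  ok_base <- function(a) grepl("^[ACGT]$", a)
  if (any(!ok_base(tab$risk_allele) | !ok_base(tab$other_allele))) {
    stop("alleles must be single bases A/C/G/T")
  }
  if (any(tab$risk_allele == tab$other_allele)) {
    stop("risk_allele equals other_allele for: ",
         paste(tab$variant_id[tab$risk_allele == tab$other_allele], collapse = ", "))
  }
  if (any(is.na(tab$pos)) || any(tab$pos < 1L)) stop("pos must be a positive 1-based integer")
  invisible(tab)
}

#' Bundled synthetic nine-SNP Type 1 diabetes GRS panel
#'
#' Returns the weight table shipped with the package. The panel mimics the
#' structure of published nine-SNP Type 1 diabetes risk scores (two
#' large-effect HLA class II tag SNPs plus seven moderate non-HLA loci),
#' but its variant ids, coordinates, weights and the \code{control_af}
#' column (control-population risk-allele frequencies used by the cohort
#' simulator) are synthetic: they were calibrated so that simulated
#' control and case score distributions match the published WTCCC
#' control [median 8.1, IQR 6.9-9.4] and Type 1 diabetes
#' [median 10.7, IQR 9.7-11.7] GRS summaries. They are not population
#' allele-frequency estimates.
#'
#' @return A \code{snp_weight_table} with nine rows and an extra
#'   \code{control_af} column.
#' @export
grs9_panel <- function() {
  load_weight_table(grs9_panel_file())
}

#' Path to the bundled synthetic panel file
#' @return File path of the installed weight-table TSV.
#' @export
grs9_panel_file <- function() {
  system.file("extdata", "grs9_weights_synthetic.tsv",
              package = "monoscreen", mustWork = TRUE)
}

#' Published characteristics of the six monogenic diabetes cases
#'
#' The six children with genetically confirmed monogenic diabetes in the
#' motivating Iranian cohort (three WFS1, one SLC19A2, one SLC29A3, one
#' GCK), with their nine-SNP Type 1 diabetes GRS and the centile of that
#' score in the WTCCC Type 1 diabetes reference cohort. These printed
#' per-child values are the study's worked example for threshold selection.
#'
#' @return A data.frame with columns \code{gene}, \code{variant_type},
#'   \code{age_at_diagnosis_years}, \code{consanguineous}, \code{grs},
#'   \code{t1d_centile}.
#' @export
monogenic_cases <- function() {
  path <- system.file("extdata", "monogenic_cases.tsv",
                      package = "monoscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
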