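#' Run the full monogenic-screening pipeline
#'
#' Orchestrates the analysis end to end on file inputs: load the weight
#' table, extract panel dosages from the VCF, compute the GRS and its
#' centile in a reference distribution, classify antibody titres, optionally
#' detect runs of homozygosity and flag consanguinity, and quantify
#' monogenic vs Type 1 diabetes discrimination. Each output file starts
#' with comment lines recording the seed and every threshold actually used,
#' and a run directory is write-once: re-running into a non-empty directory
#' is an error.
#'
#' @param weights_path Weight-table TSV (see [load_weight_table()]).
#' @param vcf_path Panel VCF.
#' @param subjects_path Subject TSV with columns \code{subject_id},
#'   \code{group} (\code{"monogenic"}/\code{"t1d"}), titre columns
#'   \code{gad}, \code{ia2}, \code{znt8} (NA = not tested) and optionally
#'   \code{known_consanguineous}.
#' @param out_dir Output directory (created; must not contain prior outputs).
#' @param reference A [ref_dist] for centile mapping (default: the WTCCC
#'   Type 1 diabetes summary).
#' @param thresholds [antibody_thresholds()].
#' @param roh_calls Optional named list (by subject id) of dense genotype
#'   call tables for [detect_roh()].
#' @param genome_size_bp Genome size for the consanguinity rule (required
#'   when \code{roh_calls} is given).
#' @param missing_policy Passed to [compute_grs()].
#' @param ci_method,n_boot,seed,grid Passed to [discriminate()].
#' @return Invisibly, a bundle list: file \code{paths}, the
#'   \code{discrimination_report}, \code{scores}, \code{calls},
#'   \code{summary_table}.
#' @export
run_pipeline <- function(weights_path, vcf_path, subjects_path, out_dir,
                         reference = grs_reference("wtccc_t1d"),
                         thresholds = antibody_thresholds(),
                         roh_calls = NULL, genome_size_bp = NULL,
                         missing_policy = "fail",
                         ci_method = "delong", n_boot = 2000L,
                         seed = 1L, grid = 0.1) {
  for (p in c(weights_path, vcf_path, subjects_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- c("scores.tsv", "antibody_calls.tsv", "roh.bed",
               "discrimination.json", "summary_table.tsv", "report.md")
  clash <- file.exists(file.path(out_dir, outputs))
  if (any(clash)) {
    stop("run directory already contains output(s): ",
         paste(outputs[clash], collapse = ", "),
         " (runs are write-once; use a fresh directory)")
  }
  stamp <- c(sprintf("# monoscreen run seed=%d ci_method=%s grid=%g", seed, ci_method, grid),
             sprintf("# antibody thresholds U/ml: gad=%g ia2=%g znt8=%g",
                     thresholds$gad, thresholds$ia2, thresholds$znt8),
             "# consanguinity rule: segments >3e6 bp covering >0.03 of genome")

  stage <- "genetic risk score"
  bundle <- tryCatch({
    weights <- load_weight_table(weights_path)
    geno <- dosages_from_vcf(vcf_path, weights)
    scores <- compute_grs(geno, weights, missing_policy = missing_policy)
    scores$centile <- round(centile_of(scores$grs, reference), 1)

    subjects <- utils::read.delim(subjects_path, stringsAsFactors = FALSE)
    if (!all(c("subject_id", "group") %in% names(subjects))) {
      stop("subject table must have subject_id and group columns")
    }
    merged <- merge(subjects, scores, by = "subject_id", sort = FALSE)

    stage <- "antibody classification"
    calls <- classify_antibodies(merged, thresholds)
    merged <- merge(merged, calls, by = "subject_id", sort = FALSE)

    stage <- "runs of homozygosity"
    roh_path <- NULL
    merged$consanguineous <- NA
    if (!is.null(roh_calls)) {
      if (is.null(genome_size_bp)) stop("genome_size_bp required with roh_calls")
      seg_list <- lapply(names(roh_calls), function(sid) {
        seg <- detect_roh(roh_calls[[sid]])
        if (nrow(seg) > 0L) seg$subject_id <- sid
        seg
      })
      names(seg_list) <- names(roh_calls)
      flags <- vapply(names(roh_calls), function(sid) {
        prof <- homozygosity_profile(sid, seg_list[[sid]], genome_size_bp)
        consanguinity_flag(prof)
      }, logical(1))
      merged$consanguineous <- flags[merged$subject_id]
      all_segs <- do.call(rbind, seg_list)
      roh_path <- file.path(out_dir, "roh.bed")
      if (!is.null(all_segs) && nrow(all_segs) > 0L) {
        write_roh_bed(all_segs, roh_path)
      } else {
        writeLines(character(), roh_path)
      }
    }
    if ("known_consanguineous" %in% names(merged)) {
      merged$consanguineous <- ifelse(is.na(merged$consanguineous),
                                      merged$known_consanguineous,
                                      merged$consanguineous | merged$known_consanguineous)
    }

    stage <- "discrimination"
    mono <- merged$grs[merged$group == "monogenic"]
    t1d <- merged$grs[merged$group == "t1d"]
    report <- NULL
    if (length(mono) > 0L && length(t1d) > 0L) {
      report <- discriminate(mono, t1d, ci_method = ci_method,
                             n_boot = n_boot, seed = seed, grid = grid)
    }

    stage <- "summary table"
    summary_tab <- summarize_groups(merged)

    stage <- "writing outputs"
    write_stamped <- function(df, file) {
      path <- file.path(out_dir, file)
      writeLines(stamp, path)
      suppressWarnings(
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, append = TRUE))
      path
    }
    paths <- list(
      scores = write_stamped(scores, "scores.tsv"),
      calls = write_stamped(calls, "antibody_calls.tsv"),
      summary = write_stamped(summary_tab, "summary_table.tsv"),
      roh = roh_path)
    disc_path <- file.path(out_dir, "discrimination.json")
    jsonlite::write_json(
      if (is.null(report)) list(note = "single-group cohort: no discrimination")
      else list(seed = seed, ci_method = ci_method,
                auc = report$auc,
                auc_ci = as.list(report$auc_ci),
                threshold = report$threshold,
                sensitivity = report$sensitivity,
                specificity = report$specificity,
                nnt = report$nnt,
                roc_points = report$roc_points),
      disc_path, auto_unbox = TRUE, digits = NA)
    paths$discrimination <- disc_path

    list(paths = paths, report = report, scores = scores, calls = calls,
         subjects = merged, summary_table = summary_tab, seed = seed)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  report_path <- file.path(out_dir, "report.md")
  writeLines(render_report(bundle), report_path)
  bundle$paths$report <- report_path
  invisible(bundle)
}

#' Group summary table for a merged subject data frame
#'
#' Builds the cohort-characteristics table (antibody positivity counts,
#' combined-positivity rows, GRS median/IQR, consanguinity) with p-values
#' for the monogenic vs Type 1 diabetes difference from [group_compare()].
#' Degrades to a single-group summary (no p-values) when only one group is
#' present.
#'
#' @param merged Data.frame with \code{group}, panel-call columns and
#'   \code{grs} (as assembled by [run_pipeline()]).
#' @return A data.frame, one row per characteristic.
#' @export
summarize_groups <- function(merged) {
  tested <- merged[!is.na(merged$tested) & merged$tested, , drop = FALSE]
  tested$at_least_one <- tested$n_pos >= 1L
  tested$two_antibodies <- tested$n_pos == 2L
  tested$three_antibodies <- tested$n_pos == 3L
  vars_ab <- c("gad_pos", "ia2_pos", "znt8_pos",
               "at_least_one", "two_antibodies", "three_antibodies")
  vars_num <- "grs"
  if (!any(is.na(merged$consanguineous))) {
    vars_flag <- "consanguineous"
  } else vars_flag <- character()

  two_groups <- length(unique(merged$group)) == 2L
  if (two_groups) {
    tab_ab <- group_compare(tested, "group", vars_ab)
    tab_rest <- group_compare(merged, "group", c(vars_num, vars_flag))
    rbind(tab_ab, tab_rest)
  } else {
    one <- function(df, v) {
      x <- df[[v]][!is.na(df[[v]])]
      s <- if (is.logical(x)) sprintf("%d (%.1f)", sum(x), 100 * mean(x))
      else {
        q <- stats::quantile(x, c(.5, .25, .75), type = 7)
        sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
      }
      data.frame(variable = v, summary = s, stringsAsFactors = FALSE)
    }
    rbind(do.call(rbind, lapply(vars_ab, function(v) one(tested, v))),
          do.call(rbind, lapply(c(vars_num, vars_flag),
                                function(v) one(merged, v))))
  }
}

#' Render a human-readable pipeline report
#'
#' Markdown summary of a pipeline bundle: cohort composition, the
#' discrimination statistics (AUC with CI, threshold, sensitivity,
#' specificity, number needed to test), antibody Venn counts and the group
#' summary table. With a single-group cohort the discrimination section is
#' replaced by an explicit notice. If \pkg{ggplot2} is installed and
#' \code{plot_dir} is given, a GRS dot plot and ROC curve are also written;
#' the textual report never depends on the plotting backend.
#'
#' @param bundle A bundle from [run_pipeline()].
#' @param plot_dir Optional directory for plot files.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle, plot_dir = NULL) {
  subj <- bundle$subjects
  lines <- c("# Monogenic diabetes screening report",
             "",
             sprintf("Subjects: %d (%d monogenic, %d Type 1 diabetes); seed %d.",
                     nrow(subj), sum(subj$group == "monogenic"),
                     sum(subj$group == "t1d"), bundle$seed),
             "")
  if (is.null(bundle$report)) {
    lines <- c(lines,
               "**Note:** only one group present; discrimination statistics",
               "cannot be computed and only the group summary is reported.",
               "")
  } else {
    r <- bundle$report
    lines <- c(lines,
               "## Discrimination",
               "",
               sprintf("- AUC: %.2f (95%% CI %.2f-%.2f, %s)",
                       r$auc, r$auc_ci[1], r$auc_ci[2], r$ci_method),
               sprintf("- Screening threshold: GRS < %.1f", r$threshold),
               sprintf("- Sensitivity: %.2f; specificity: %.2f",
                       r$sensitivity, r$specificity),
               sprintf("- Number needed to test per diagnosis: %s",
                       ifelse(is.na(r$nnt), "undefined", r$nnt)),
               "")
  }
  vc <- venn_counts(bundle$calls)
  lines <- c(lines,
             "## Antibody panel",
             "",
             sprintf("- Tested: %d", vc$n_tested),
             sprintf("- GAD only %d, IA2 only %d, ZnT8 only %d; two antibodies %d; three %d",
                     vc$gad_only, vc$ia2_only, vc$znt8_only,
                     vc$exactly_two, vc$all_three),
             sprintf("- At least one antibody: %d; none: %d",
                     vc$at_least_one, vc$none),
             "",
             "## Group summary",
             "")
  tab <- bundle$summary_table
  lines <- c(lines,
             paste("|", paste(names(tab), collapse = " | "), "|"),
             paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
             vapply(seq_len(nrow(tab)), function(i) {
               paste("|", paste(vapply(tab[i, ], as.character, character(1)),
                                collapse = " | "), "|")
             }, character(1)))

  if (!is.null(plot_dir) && requireNamespace("ggplot2", quietly = TRUE)) {
    if (!dir.exists(plot_dir)) dir.create(plot_dir, recursive = TRUE)
    gp <- ggplot2::ggplot(subj, ggplot2::aes(x = group, y = grs)) +
      ggplot2::geom_jitter(width = 0.15, height = 0) +
      ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                            width = 0.4, colour = "red") +
      ggplot2::labs(y = "Type 1 diabetes GRS", x = NULL)
    ggplot2::ggsave(file.path(plot_dir, "grs_dotplot.png"), gp,
                    width = 4, height = 4, dpi = 150)
    if (!is.null(bundle$report)) {
      rp <- ggplot2::ggplot(bundle$report$roc_points,
                            ggplot2::aes(x = fpr, y = tpr)) +
        ggplot2::geom_step() +
        ggplot2::geom_abline(linetype = 2) +
        ggplot2::labs(x = "1 - specificity", y = "Sensitivity")
      ggplot2::ggsave(file.path(plot_dir, "roc.png"), rp,
                      width = 4, height = 4, dpi = 150)
    }
    lines <- c(lines, "", sprintf("Plots written to %s.", plot_dir))
  }
  lines
}
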