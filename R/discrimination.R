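#' Mann-Whitney AUC between two score vectors
#'
#' The area under the ROC curve computed as the Mann-Whitney probability:
#' (concordant pairs + half ties) / (n_pos * n_neg). With
#' \code{orientation = "higher_in_pos"} a pair is concordant when the
#' positive-class score exceeds the negative-class score;
#' \code{"lower_in_pos"} reverses this (the orientation used when monogenic
#' cases, with their low Type 1 diabetes GRS, are the screening positives).
#'
#' @param scores_pos,scores_neg Non-empty numeric vectors for the positive
#'   and negative class.
#' @param orientation \code{"higher_in_pos"} (default) or
#'   \code{"lower_in_pos"}.
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg,
                             orientation = c("higher_in_pos", "lower_in_pos")) {
  orientation <- match.arg(orientation)
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score vectors must be non-empty")
  }
  if (orientation == "lower_in_pos") {
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  n1 <- length(scores_pos)
  n0 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))  # midranks handle ties
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Full stepwise ROC curve over all distinct score thresholds, from (0,0)
#' to (1,1), with both coordinates non-decreasing.
#'
#' @inheritParams auc_mann_whitney
#' @return Data.frame with columns \code{fpr}, \code{tpr}.
#' @export
roc_points <- function(scores_pos, scores_neg,
                       orientation = c("higher_in_pos", "lower_in_pos")) {
  orientation <- match.arg(orientation)
  if (orientation == "lower_in_pos") {
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  cuts <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tpr <- vapply(cuts, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(scores_neg >= t), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' 95\% confidence interval for the AUC
#'
#' DeLong's asymptotic interval (via \pkg{pROC}) or a seeded,
#' class-stratified percentile bootstrap. A degenerate point AUC of exactly
#' 0 or 1 has no DeLong variance, so the bootstrap is used instead with a
#' warning. Bounds are clamped to [0, 1].
#'
#' @inheritParams auc_mann_whitney
#' @param method \code{"delong"} (default) or \code{"bootstrap"}.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap (required for reproducibility).
#' @return Numeric vector \code{c(lo, hi)}.
#' @export
auc_ci <- function(scores_pos, scores_neg,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000L, seed = 1L,
                   orientation = c("higher_in_pos", "lower_in_pos")) {
  method <- match.arg(method)
  orientation <- match.arg(orientation)
  if (length(scores_pos) < 2L || length(scores_neg) < 2L) {
    stop("need at least 2 scores per class for a confidence interval")
  }
  if (orientation == "lower_in_pos") {
    scores_pos <- -scores_pos
    scores_neg <- -scores_neg
  }
  point <- auc_mann_whitney(scores_pos, scores_neg)
  if (method == "delong" && (point == 0 || point == 1)) {
    warning("degenerate AUC of ", point,
            "; falling back to stratified bootstrap interval")
    method <- "bootstrap"
  }
  if (method == "delong") {
    roc <- pROC::roc(response = c(rep(1L, length(scores_pos)),
                                  rep(0L, length(scores_neg))),
                     predictor = c(scores_pos, scores_neg),
                     direction = "<", levels = c(0L, 1L), quiet = TRUE)
    ci <- pROC::ci.auc(roc, method = "delong")
    lo <- ci[1L]; hi <- ci[3L]
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      auc_mann_whitney(sample(scores_pos, replace = TRUE),
                       sample(scores_neg, replace = TRUE))
    }, numeric(1))
    qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
    lo <- qs[1L]; hi <- qs[2L]
  }
  c(lo = max(0, min(lo, point)), hi = min(1, max(hi, point)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Full-sensitivity screening threshold
#'
#' Chooses the lowest threshold on a fixed grid that classifies every
#' monogenic case as screen-positive under the rule
#' \emph{score < threshold => screen positive}: the smallest grid multiple
#' strictly greater than the largest monogenic score (with the printed
#' one-decimal grid, the six monogenic scores of the study give 9.2).
#' Sensitivity is then computed on the monogenic scores (1 by construction)
#' and specificity on the Type 1 diabetes scores (fraction at or above the
#' threshold).
#'
#' @param scores_pos Monogenic (screening-positive class) GRS values; lower
#'   scores indicate the positive class.
#' @param scores_neg Type 1 diabetes GRS values.
#' @param rule Threshold rule; only \code{"full_sensitivity"} is defined.
#' @param grid Threshold resolution (default 0.1, the printed precision).
#' @return List: \code{threshold}, \code{sensitivity}, \code{specificity}.
#'   When every negative also falls below the threshold the specificity is
#'   simply 0; this is not an error.
#' @export
choose_threshold <- function(scores_pos, scores_neg,
                             rule = "full_sensitivity", grid = 0.1) {
  rule <- match.arg(rule, "full_sensitivity")
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score vectors must be non-empty")
  }
  m <- max(scores_pos)
  thr <- grid * ceiling(m / grid - 1e-9)
  if (thr <= m + 1e-12) thr <- thr + grid
  thr <- round(thr / grid) * grid
  list(threshold = thr,
       sensitivity = mean(scores_pos < thr),
       specificity = mean(scores_neg >= thr))
}

#' Number needed to test per monogenic diagnosis
#'
#' Expected number of screen-positive children who must undergo genetic
#' testing to confirm one monogenic case, from the screen's sensitivity and
#' specificity and the class sizes:
#' \code{ceiling((sens * n_pos + (1 - spec) * n_neg) / (sens * n_pos))}.
#' At the study's operating point (sensitivity 1.00, specificity 0.82,
#' 6 monogenic vs 121 Type 1 diabetes) this is 5.
#'
#' @param n_pos,n_neg Class sizes (monogenic, Type 1 diabetes).
#' @param sensitivity,specificity Screen operating characteristics in [0, 1].
#' @return Integer number needed to test.
#' @export
number_needed_to_test <- function(n_pos, n_neg, sensitivity, specificity) {
  stopifnot(n_pos >= 0, n_neg >= 0,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  detected <- sensitivity * n_pos
  if (detected == 0) stop("no detected cases: number needed to test undefined")
  as.integer(ceiling((detected + (1 - specificity) * n_neg) / detected))
}

#' Two-group comparison table
#'
#' Compares variables between two groups the way small clinical cohorts are
#' summarized: proportions by chi-squared test, switching to Fisher's exact
#' test when any expected cell count is below 5 (unavoidable with a group of
#' six); continuous variables by Wilcoxon rank-sum, exact when both groups
#' have 25 or fewer observations, otherwise the normal approximation with
#' continuity correction. Constant variables are reported as untestable
#' rather than raising an error. Binary variables are summarized as
#' "n (\%)", continuous ones as "median (IQR)".
#'
#' @param data Data.frame of per-subject records.
#' @param group_var Name of a two-level grouping column.
#' @param variables Character vector of columns to compare (logical/factor
#'   columns are treated as proportions, numeric as continuous).
#' @return Data.frame: \code{variable}, one summary column per group,
#'   \code{p_value}, \code{test_used}.
#' @export
group_compare <- function(data, group_var, variables) {
  g <- data[[group_var]]
  if (is.null(g)) stop("group_var not found: ", group_var)
  g <- factor(g)
  if (nlevels(g) != 2L) stop("group_var must have exactly two levels")
  lv <- levels(g)

  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.null(x)) stop("variable not found: ", v)
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; gg <- g[keep]
    summarize <- function(sub) {
      if (is.logical(sub) || is.factor(sub) || is.character(sub)) {
        sub <- as.logical(sub)
        sprintf("%d (%.1f)", sum(sub), 100 * mean(sub))
      } else {
        q <- stats::quantile(sub, c(0.5, 0.25, 0.75), type = 7)
        sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
      }
    }
    s1 <- summarize(x[gg == lv[1]])
    s2 <- summarize(x[gg == lv[2]])

    if (length(unique(x)) < 2L) {
      return(data.frame(variable = v, g1 = s1, g2 = s2,
                        p_value = NA_real_, test_used = "untestable (constant)",
                        stringsAsFactors = FALSE))
    }
    if (is.logical(x) || is.factor(x) || is.character(x)) {
      tab <- table(gg, as.logical(x))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = TRUE)$p.value
        test <- "chi-squared"
      }
    } else {
      exact <- all(table(gg) <= 25L)
      # with ties R silently needs the normal approximation even when exact
      # is requested; the warning is expected, not actionable
      p <- suppressWarnings(
        stats::wilcox.test(x ~ gg, exact = exact, correct = !exact)$p.value)
      test <- if (exact) "wilcoxon (exact)" else "wilcoxon (normal approx.)"
    }
    data.frame(variable = v, g1 = s1, g2 = s2,
               p_value = signif(p, 3), test_used = test,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lv
  out
}

#' Discrimination report: monogenic vs Type 1 diabetes
#'
#' End-to-end ROC analysis of a GRS: Mann-Whitney AUC with 95\% CI,
#' full-sensitivity screening threshold, specificity at that threshold,
#' number needed to test, and the ROC curve. Orientation is fixed to the
#' study's: monogenic cases are screening-positive and carry \emph{lower}
#' scores.
#'
#' @param scores_monogenic,scores_t1d GRS vectors per group.
#' @param ci_method \code{"delong"} or \code{"bootstrap"} (see [auc_ci()]).
#' @param n_boot,seed Bootstrap controls.
#' @param grid Threshold grid (default 0.1).
#' @return An object of class \code{discrimination_report}: list with
#'   \code{auc}, \code{auc_ci}, \code{threshold}, \code{sensitivity},
#'   \code{specificity}, \code{nnt}, \code{roc_points}, \code{n_monogenic},
#'   \code{n_t1d}.
#' @export
discriminate <- function(scores_monogenic, scores_t1d,
                         ci_method = c("delong", "bootstrap"),
                         n_boot = 2000L, seed = 1L, grid = 0.1) {
  ci_method <- match.arg(ci_method)
  auc <- auc_mann_whitney(scores_monogenic, scores_t1d,
                          orientation = "lower_in_pos")
  ci <- auc_ci(scores_monogenic, scores_t1d, method = ci_method,
               n_boot = n_boot, seed = seed, orientation = "lower_in_pos")
  thr <- choose_threshold(scores_monogenic, scores_t1d, grid = grid)
  nnt <- if (thr$sensitivity > 0) {
    number_needed_to_test(length(scores_monogenic), length(scores_t1d),
                          thr$sensitivity, thr$specificity)
  } else NA_integer_
  structure(list(auc = auc, auc_ci = ci,
                 threshold = thr$threshold,
                 sensitivity = thr$sensitivity,
                 specificity = thr$specificity,
                 nnt = nnt,
                 roc_points = roc_points(scores_monogenic, scores_t1d,
                                         orientation = "lower_in_pos"),
                 n_monogenic = length(scores_monogenic),
                 n_t1d = length(scores_t1d),
                 ci_method = ci_method, seed = seed),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("GRS discrimination, %d monogenic vs %d Type 1 diabetes\n",
              x$n_monogenic, x$n_t1d))
  cat(sprintf("  AUC %.2f (95%% CI %.2f-%.2f, %s)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$ci_method))
  cat(sprintf("  screen positive if GRS < %.1f: sensitivity %.2f, specificity %.2f\n",
              x$threshold, x$sensitivity, x$specificity))
  if (!is.na(x$nnt)) {
    cat(sprintf("  number needed to test per monogenic diagnosis: %d\n", x$nnt))
  }
  invisible(x)
}
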