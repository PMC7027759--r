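test_that("Mann-Whitney AUC handles separation, ties and orientation", {
  expect_equal(auc_mann_whitney(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(auc_mann_whitney(2, 2), 0.5)
  expect_equal(auc_mann_whitney(c(1, 2), c(5, 6), "lower_in_pos"), 1)
  expect_error(auc_mann_whitney(numeric(), 1), "non-empty")
})

test_that("AUC equals the all-pairs count oracle and pROC", {
  set.seed(12)
  for (rep in 1:5) {
    pos <- round(rnorm(20, 1), 1)  # rounding creates ties
    neg <- round(rnorm(20, 0), 1)
    a <- auc_mann_whitney(pos, neg)
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(a, mean(pairs), tolerance = 1e-12)
    proc <- as.numeric(pROC::auc(
      response = rep(1:0, each = 20), predictor = c(pos, neg),
      direction = "<", quiet = TRUE))
    expect_equal(a, proc, tolerance = 1e-12)
  }
})

test_that("AUC flips to its complement when classes swap", {
  set.seed(4)
  pos <- rnorm(15, 1); neg <- rnorm(25)
  expect_equal(auc_mann_whitney(pos, neg) + auc_mann_whitney(neg, pos), 1)
})

test_that("AUC equals the trapezoidal area under the ROC curve", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- round(rnorm(15, 0.8), 1)
    neg <- round(rnorm(30), 1)
    rc <- roc_points(pos, neg)
    expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
    expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    trap <- sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
    expect_equal(trap, auc_mann_whitney(pos, neg), tolerance = 1e-12)
  }
})

test_that("confidence intervals contain the point AUC and are seeded", {
  set.seed(2)
  pos <- rnorm(6, 8.4, 0.6)
  neg <- rnorm(121, 10.8, 1.4)
  for (m in c("delong", "bootstrap")) {
    ci <- auc_ci(pos, neg, method = m, seed = 5, orientation = "lower_in_pos")
    a <- auc_mann_whitney(pos, neg, "lower_in_pos")
    expect_lt(ci[1], ci[2])
    expect_gte(a, ci[1]); expect_lte(a, ci[2])
  }
  b1 <- auc_ci(pos, neg, method = "bootstrap", seed = 9, n_boot = 500)
  b2 <- auc_ci(pos, neg, method = "bootstrap", seed = 9, n_boot = 500)
  expect_identical(b1, b2)
})

test_that("degenerate separation falls back from DeLong to bootstrap", {
  expect_warning(
    ci <- auc_ci(c(10, 11, 12), c(1, 2, 3), method = "delong", seed = 3),
    "degenerate")
  expect_true(ci[1] <= 1 && ci[2] <= 1)
})

test_that("full-sensitivity threshold reproduces the printed 9.2 example", {
  mono <- c(7.002, 9.101, 8.824, 9.135, 8.004, 8.151)
  set.seed(33)
  t1d <- rnorm(121, 10.8, 1.41)
  thr <- choose_threshold(mono, t1d)
  expect_equal(thr$threshold, 9.2)
  expect_equal(thr$sensitivity, 1)

  # a single monogenic score below every T1D score: perfect screen
  perfect <- choose_threshold(5, c(9, 10, 11))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("a grid-aligned maximum still gets a strictly greater threshold", {
  thr <- choose_threshold(c(8.0, 9.2), c(10, 11))
  expect_gt(thr$threshold, 9.2)
  expect_equal(thr$threshold, 9.3)
  expect_equal(thr$sensitivity, 1)
})

test_that("threshold rule always attains sensitivity 1 on training data", {
  set.seed(61)
  for (rep in 1:10) {
    mono <- rnorm(6, 8.4, 0.8)
    t1d <- rnorm(50, 10.8, 1.4)
    thr <- choose_threshold(mono, t1d)
    expect_equal(thr$sensitivity, 1)
    # brute-force recount of both operating characteristics
    expect_equal(thr$sensitivity, mean(mono < thr$threshold))
    expect_equal(thr$specificity, mean(t1d >= thr$threshold))
  }
})

test_that("fully overlapping classes degrade to specificity 0, not an error", {
  thr <- choose_threshold(c(10, 11), c(1, 2, 3))
  expect_equal(thr$sensitivity, 1)
  expect_equal(thr$specificity, 0)
})

test_that("number needed to test reproduces the study operating point", {
  expect_equal(number_needed_to_test(6, 121, 1, 0.82), 5L)
  expect_equal(number_needed_to_test(6, 121, 1, 1), 1L)
  expect_error(number_needed_to_test(6, 121, 0, 0.8), "undefined")
})

test_that("number needed to test matches a large-n simulation oracle", {
  set.seed(88)
  for (rep in 1:5) {
    sens <- runif(1, 0.6, 1); spec <- runif(1, 0.5, 0.95)
    n_pos <- sample(4:10, 1); n_neg <- sample(80:200, 1)
    nnt <- number_needed_to_test(n_pos, n_neg, sens, spec)
    # expected screen-positives per detected case, by direct simulation
    B <- 20000
    detected <- rbinom(B, n_pos, sens)
    false_pos <- rbinom(B, n_neg, 1 - spec)
    sim <- mean(detected + false_pos) / mean(detected)
    expect_lte(abs(nnt - sim), 1)
  }
})

test_that("group comparison switches to exact tests for sparse tables", {
  df <- data.frame(
    group = c(rep("monogenic", 6), rep("t1d", 119)),
    ab_pos = c(rep(FALSE, 6), rep(TRUE, 84), rep(FALSE, 35)))
  tab <- group_compare(df, "group", "ab_pos")
  expect_equal(tab$test_used, "fisher")
  expect_equal(tab$p_value, 0.000959, tolerance = 1e-3)  # prints as 0.001

  big <- data.frame(group = rep(c("a", "b"), each = 200),
                    flag = rep(c(TRUE, FALSE, TRUE, FALSE),
                               times = c(120, 80, 60, 140)))
  tab2 <- group_compare(big, "group", "flag")
  expect_equal(tab2$test_used, "chi-squared")
})

test_that("identical groups give p = 1 and constants are untestable", {
  df <- data.frame(group = rep(c("a", "b"), each = 10),
                   x = rep(c(1, 2, 3, 4, 5), 4),
                   const = 1)
  tab <- group_compare(df, "group", c("x", "const"))
  expect_equal(tab$p_value[1], 1)
  expect_match(tab$test_used[2], "untestable")
})

test_that("wilcoxon variant follows the per-group size rule", {
  small <- data.frame(group = rep(c("a", "b"), each = 20), y = rnorm(40))
  big <- data.frame(group = rep(c("a", "b"), each = 40), y = rnorm(80))
  expect_match(group_compare(small, "group", "y")$test_used, "exact")
  expect_match(group_compare(big, "group", "y")$test_used, "normal approx")
})

test_that("discriminate assembles a coherent report", {
  mono <- monogenic_cases()$grs
  set.seed(10)
  t1d <- rnorm(121, 10.8, 1.41)
  rep_ <- discriminate(mono, t1d, seed = 10)
  expect_s3_class(rep_, "discrimination_report")
  expect_gte(rep_$auc, 0); expect_lte(rep_$auc, 1)
  expect_gte(rep_$auc, rep_$auc_ci[1]); expect_lte(rep_$auc, rep_$auc_ci[2])
  expect_equal(rep_$sensitivity, 1)
  expect_gte(rep_$nnt, 1)
  out <- capture.output(print(rep_))
  expect_match(out[2], "AUC")
})
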