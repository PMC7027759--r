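test_that("case allele frequency preserves the allele-level odds ratio", {
  expect_equal(case_allele_freq(0.3, 2), 0.6 / 1.3)
  expect_equal(case_allele_freq(0.42, 1), 0.42)
  # monotone approach to 1 as the odds ratio grows
  ors <- c(1, 2, 5, 20, 100, 1e4)
  p1s <- case_allele_freq(0.3, ors)
  expect_true(all(diff(p1s) > 0))
  expect_gt(p1s[length(ors)], 0.999)
  expect_error(case_allele_freq(0, 2), "strictly inside")
  expect_error(case_allele_freq(1, 2), "strictly inside")
  expect_error(case_allele_freq(0.3, -1), "positive")

  # recompute the odds ratio from a 2x2 table of 1e6 simulated alleles
  set.seed(100)
  p0 <- 0.3; or_ <- 2
  p1 <- case_allele_freq(p0, or_)
  case_alleles <- rbinom(1, 1e6, p1)
  ctrl_alleles <- rbinom(1, 1e6, p0)
  or_hat <- (case_alleles / (1e6 - case_alleles)) /
    (ctrl_alleles / (1e6 - ctrl_alleles))
  expect_equal(or_hat, or_, tolerance = 0.02)
})

test_that("genotype simulation is seeded and matches target frequencies", {
  cfg <- sim_config(seed = 5)
  g1 <- simulate_genotypes(cfg, "t1d", n = 500)
  g2 <- simulate_genotypes(cfg, "t1d", n = 500)
  expect_identical(g1$dosage, g2$dosage)  # pure function of config + seed

  g <- simulate_genotypes(cfg, "t1d", n = 10000)
  p_hat <- colMeans(g$dosage) / 2
  se <- sqrt(cfg$p1 * (1 - cfg$p1) / (2 * 10000))
  expect_true(all(abs(p_hat - cfg$p1) < 3 * se + 1e-9))

  gm <- simulate_genotypes(cfg, "control_like_monogenic", n = 10000)
  p_hat0 <- colMeans(gm$dosage) / 2
  se0 <- sqrt(cfg$p0 * (1 - cfg$p0) / (2 * 10000))
  expect_true(all(abs(p_hat0 - cfg$p0) < 3 * se0 + 1e-9))
})

test_that("simulated group scores are ordered T1D above monogenic", {
  cfg <- sim_config(seed = 77)
  w <- cfg$panel$weight
  ordered <- vapply(1:500, function(r) {
    gt <- simulate_genotypes(cfg, "t1d", seed = 30000 + r)
    gm <- simulate_genotypes(cfg, "control_like_monogenic", seed = 60000 + r)
    median(gt$dosage %*% w) > median(gm$dosage %*% w)
  }, logical(1))
  expect_gte(mean(ordered), 0.99)
})

test_that("simulated score distributions bracket the published summaries", {
  # medians/IQRs averaged over seeds, compared to T1D 10.7-10.8 (9.7-11.7)
  # and control-like 8.1 (6.9-9.4); half-unit tolerance on each landmark
  cfg <- sim_config(seed = 3)
  w <- cfg$panel$weight
  qs_t1d <- t(vapply(1:20, function(r) {
    g <- simulate_genotypes(cfg, "t1d", n = 121, seed = 1000 + r)
    quantile(g$dosage %*% w, c(0.25, 0.5, 0.75), type = 7)
  }, numeric(3)))
  m <- colMeans(qs_t1d)
  expect_lt(abs(m[2] - 10.75), 0.5)
  expect_lt(abs(m[1] - 9.7), 0.5)
  expect_lt(abs(m[3] - 11.65), 0.5)

  qs_ctl <- t(vapply(1:20, function(r) {
    g <- simulate_genotypes(cfg, "control_like_monogenic", n = 121,
                            seed = 2000 + r)
    quantile(g$dosage %*% w, c(0.25, 0.5, 0.75), type = 7)
  }, numeric(3)))
  mc <- colMeans(qs_ctl)
  expect_lt(abs(mc[2] - 8.1), 0.5)
  expect_lt(abs(mc[1] - 6.9), 0.6)
  expect_lt(abs(mc[3] - 9.4), 0.5)
})

test_that("antibody marginals hit their targets and monogenic stay negative", {
  cfg <- sim_config(seed = 13)
  n <- 5000
  ab <- simulate_antibodies(cfg, rep("t1d", n))
  calls <- classify_antibodies(
    data.frame(subject_id = as.character(1:n), ab))
  targets <- cfg$antibody_rates
  for (a in 1:3) {
    rate <- mean(calls[[paste0(c("gad", "ia2", "znt8")[a], "_pos")]])
    se <- sqrt(targets[a] * (1 - targets[a]) / n)
    expect_lt(abs(rate - targets[a]), 3 * se + 0.005)
  }
  # triple-positive rate matches the calibration target
  expect_lt(abs(mean(calls$n_pos == 3) - cfg$triple_rate), 0.02)

  mono <- simulate_antibodies(cfg, rep("monogenic", 500))
  mono_calls <- classify_antibodies(
    data.frame(subject_id = as.character(1:500), mono))
  expect_equal(sum(mono_calls$n_pos), 0L)
})

test_that("zero factor loading makes the three assays independent", {
  cfg <- sim_config(seed = 19, antibody_loading = 0)
  n <- 20000
  ab <- simulate_antibodies(cfg, rep("t1d", n))
  calls <- classify_antibodies(data.frame(subject_id = as.character(1:n), ab))
  triple <- mean(calls$n_pos == 3)
  indep <- prod(cfg$antibody_rates)
  expect_lt(abs(triple - indep), 3 * sqrt(indep * (1 - indep) / n) + 0.002)
})

test_that("infeasible antibody targets raise a calibration error", {
  expect_error(calibrate_antibody_loading(c(0.5, 0.3, 0.25), 0.4),
               "infeasible")
})

test_that("calibrated loading reproduces the target triple rate in the model", {
  rates <- c(59, 39, 31) / 121
  lam <- calibrate_antibody_loading(rates, 12 / 121)
  expect_gt(lam, 0)  # printed overlap exceeds independence
  # forward-check by one-dimensional integration
  cuts <- qnorm(1 - rates); s <- sqrt(1 - lam^2)
  p3 <- integrate(function(z) {
    dnorm(z) * pnorm((lam * z - cuts[1]) / s) *
      pnorm((lam * z - cuts[2]) / s) * pnorm((lam * z - cuts[3]) / s)
  }, -8, 8)$value
  expect_equal(p3, 12 / 121, tolerance = 1e-4)
})

test_that("planted ROH segments are recovered by the detector", {
  cfg <- small_roh_config(seed = 23)
  sim <- simulate_roh(cfg, consanguineous = TRUE, seed = 23001)
  seg <- detect_roh(sim$calls)
  big_truth <- sim$truth[sim$truth$length_bp > 3e6, , drop = FALSE]
  expect_gt(nrow(big_truth), 0L)
  # each planted segment (long ones may be split by residual het calls)
  # must be covered almost entirely by detected segments
  overlap_len <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1) + 1)
  for (k in seq_len(nrow(big_truth))) {
    same <- seg[seg$chrom == big_truth$chrom[k], , drop = FALSE]
    cov <- sum(mapply(overlap_len, same$start, same$end,
                      big_truth$start[k], big_truth$end[k]))
    expect_gte(cov / big_truth$length_bp[k], 0.8)
  }
})

test_that("the full cohort generator is deterministic and self-consistent", {
  cfg <- small_roh_config(seed = 31, n_t1d = 20L, n_monogenic = 4L,
                          genome_size_bp = 1e8, n_chrom = 2L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(lapply(c1$roh, `[[`, "truth"),
                   lapply(c2$roh, `[[`, "truth"))

  # true_grs equals scoring the dosage matrix
  sc <- compute_grs(c1$genotypes, cfg$panel)
  expect_equal(sc$grs, c1$subjects$true_grs)

  # antibody Venn partition survives generation -> classification
  calls <- classify_antibodies(c1$subjects)
  vc <- venn_counts(calls)
  expect_equal(vc$at_least_one + vc$none, vc$n_tested)
  expect_equal(vc$n_tested, nrow(c1$subjects))
})

test_that("emitted files form a valid, round-trippable VCF 4.2 bundle", {
  cfg <- sim_config(seed = 47, n_t1d = 10L, n_monogenic = 3L)
  coh <- simulate_cohort(cfg, include_roh = FALSE)
  dir <- tempfile("bundle")
  paths <- emit_cohort(coh, dir)
  expect_true(all(file.exists(unlist(paths))))

  lines <- readLines(paths$vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_equal(sum(!startsWith(lines, "#")), 9L)  # one row per panel SNP
  # parses cleanly with a standard VCF reader
  expect_silent(v <- vcfR::read.vcfR(paths$vcf, verbose = FALSE))
  expect_equal(ncol(vcfR::extract.gt(v, "GT")), 13L)

  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$seed, 47L)
  expect_equal(unname(truth$dosage), unname(coh$genotypes$dosage))

  subj <- read.delim(paths$subjects)
  expect_equal(subj$subject_id, coh$subjects$subject_id)
  expect_equal(subj$true_grs, coh$subjects$true_grs)
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(), "seed is mandatory")
  bad_panel <- grs9_panel(); bad_panel$control_af <- NULL
  expect_error(sim_config(seed = 1, panel = bad_panel), "control_af")
  expect_error(sim_config(seed = 1, consanguinity_fraction = 1.2), "\\[0, 1\\]")
  cfg <- sim_config(seed = 1, genome_size_bp = 1e7, n_chrom = 2L,
                    consang_len_scale = 4e7)
  expect_error(simulate_roh(cfg, TRUE, seed = 2), "longer than a chromosome")
})
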