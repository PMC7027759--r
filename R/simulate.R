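# hierarchical sub-seed: distinct reproducible stream per subsystem
.sub_seed <- function(seed, k) {
  (as.integer(seed) %% 2000000L) * 1000L + as.integer(k)
}

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Case-population risk-allele frequency under a log-additive model
#'
#' Given the control-population risk-allele frequency p0 and the per-allele
#' odds ratio, returns the case frequency p1 such that allele-level odds in
#' cases / odds in controls equals the odds ratio:
#' \code{p1 = p0 * or / (1 - p0 + p0 * or)}.
#'
#' @param p0 Control frequency, strictly inside (0, 1).
#' @param or_ Per-allele odds ratio, > 0.
#' @return Case frequency in (0, 1).
#' @export
case_allele_freq <- function(p0, or_) {
  if (any(p0 <= 0) || any(p0 >= 1)) stop("p0 must lie strictly inside (0, 1)")
  if (any(or_ <= 0)) stop("odds ratio must be positive")
  p0 * or_ / (1 - p0 + p0 * or_)
}

#' Calibrate the shared-factor loading of the antibody model
#'
#' The simulator's three assays are positive when latent normal variables
#' \eqn{u_a = \lambda z + \sqrt{1-\lambda^2}\, e_a} exceed per-assay cut-offs
#' chosen to give the target marginal positivity rates; the shared factor z
#' induces the positive cross-assay dependence seen in real panels, where
#' triple-positive counts exceed the independence expectation. This function
#' finds by bisection the loading \eqn{\lambda} for which the model's
#' triple-positive probability (a one-dimensional integral over z) equals
#' the target.
#'
#' @param rates Length-3 marginal positivity rates (gad, ia2, znt8).
#' @param triple_rate Target triple-positive probability.
#' @param tol Bisection tolerance on the triple rate.
#' @return Loading in [0, 1).
#' @export
calibrate_antibody_loading <- function(rates, triple_rate, tol = 1e-6) {
  if (any(rates <= 0) || any(rates >= 1)) stop("marginal rates must be in (0, 1)")
  if (triple_rate > min(rates)) {
    stop("infeasible target: triple-positive rate exceeds a marginal rate")
  }
  cuts <- stats::qnorm(1 - rates)
  triple_prob <- function(lambda) {
    if (lambda == 0) return(prod(rates))
    s <- sqrt(1 - lambda^2)
    stats::integrate(function(z) {
      stats::dnorm(z) *
        stats::pnorm((lambda * z - cuts[1]) / s) *
        stats::pnorm((lambda * z - cuts[2]) / s) *
        stats::pnorm((lambda * z - cuts[3]) / s)
    }, -8, 8, rel.tol = 1e-9)$value
  }
  if (triple_rate <= prod(rates)) return(0)
  lo <- 0; hi <- 0.999
  if (triple_prob(hi) < triple_rate) stop("infeasible target triple rate")
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (triple_prob(mid) < triple_rate - tol) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulation configuration for a synthetic screening cohort
#'
#' Bundles every parameter of the cohort generator. The defaults are the
#' study conditions of the motivating cohort: 121 Type 1 diabetes and 6
#' monogenic children; marginal antibody positivity rates 59/121, 39/121
#' and 31/121 for GAD, IA2 and ZnT8 with a triple-positive target of
#' 12/121 (monogenic children are always antibody-negative); a 32.2\%
#' consanguinity rate; and the bundled synthetic panel whose weights and
#' control frequencies were calibrated to the published WTCCC score
#' summaries. Type 1 diabetes genotypes use per-variant case frequencies
#' derived from the control frequencies through the per-allele odds ratio
#' \code{exp(weight)}; monogenic children carry the background
#' (control-like) allele load.
#'
#' @param seed Integer seed (mandatory; every stochastic operation is a pure
#'   function of config + seed).
#' @param n_t1d,n_monogenic Group sizes.
#' @param panel Weight table with a \code{control_af} column.
#' @param antibody_rates Marginal positivity rates (gad, ia2, znt8) among
#'   Type 1 diabetes subjects.
#' @param triple_rate Target triple-positive rate among Type 1 diabetes
#'   subjects.
#' @param antibody_loading Shared-factor loading; \code{NULL} (default)
#'   calibrates it to \code{triple_rate} by bisection, 0 makes assays
#'   independent.
#' @param thresholds [antibody_thresholds()] used to anchor titre scales.
#' @param consanguinity_fraction Fraction of subjects simulated as offspring
#'   of consanguineous unions.
#' @param genome_size_bp,n_chrom,marker_spacing_bp Genome model for the
#'   dense ROH marker panel.
#' @param het_rate Background per-marker heterozygosity outside ROH.
#' @param roh_err Residual heterozygosity inside true ROH segments.
#' @param consang_n_seg,consang_len_shape,consang_len_scale Poisson mean and
#'   gamma length model for consanguineous ROH segments (defaults give
#'   about 12 segments averaging 20 Mb, ~8\% of a 3 Gb genome, the level
#'   expected for first-cousin offspring).
#' @param outbred_n_seg,outbred_len_shape,outbred_len_scale Sporadic short
#'   homozygous stretches in outbred subjects (mean ~1.2 Mb, below the 3 Mb
#'   rule).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_t1d = 121L, n_monogenic = 6L,
                       panel = grs9_panel(),
                       antibody_rates = c(gad = 59, ia2 = 39, znt8 = 31) / 121,
                       triple_rate = 12 / 121,
                       antibody_loading = NULL,
                       thresholds = antibody_thresholds(),
                       consanguinity_fraction = 41 / 127,
                       genome_size_bp = 3e9, n_chrom = 22L,
                       marker_spacing_bp = 5e4,
                       het_rate = 0.32, roh_err = 0.002,
                       consang_n_seg = 12, consang_len_shape = 4,
                       consang_len_scale = 5e6,
                       outbred_n_seg = 3, outbred_len_shape = 4,
                       outbred_len_scale = 3e5) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(panel$control_af)) stop("panel must carry a control_af column")
  p0 <- panel$control_af
  if (any(p0 <= 0) || any(p0 >= 1)) stop("control_af must lie inside (0, 1)")
  if (any(antibody_rates < 0) || any(antibody_rates > 1)) {
    stop("antibody rates must lie in [0, 1]")
  }
  if (consanguinity_fraction < 0 || consanguinity_fraction > 1) {
    stop("consanguinity_fraction must lie in [0, 1]")
  }
  if (is.null(antibody_loading)) {
    antibody_loading <- calibrate_antibody_loading(antibody_rates, triple_rate)
  }
  chrom_size <- genome_size_bp / n_chrom
  max_len <- max(c(consang_len_shape * consang_len_scale * 10,
                   outbred_len_shape * outbred_len_scale * 10))
  if (chrom_size < 1) stop("genome too small for the chromosome count")
  structure(list(seed = as.integer(seed),
                 n_t1d = as.integer(n_t1d), n_monogenic = as.integer(n_monogenic),
                 panel = panel, p0 = p0,
                 p1 = case_allele_freq(p0, exp(panel$weight)),
                 antibody_rates = antibody_rates, triple_rate = triple_rate,
                 antibody_loading = antibody_loading,
                 thresholds = thresholds,
                 consanguinity_fraction = consanguinity_fraction,
                 genome_size_bp = genome_size_bp, n_chrom = as.integer(n_chrom),
                 chrom_size_bp = chrom_size,
                 marker_spacing_bp = marker_spacing_bp,
                 het_rate = het_rate, roh_err = roh_err,
                 consang_n_seg = consang_n_seg,
                 consang_len_shape = consang_len_shape,
                 consang_len_scale = consang_len_scale,
                 outbred_n_seg = outbred_n_seg,
                 outbred_len_shape = outbred_len_shape,
                 outbred_len_scale = outbred_len_scale,
                 max_seg_len = max_len),
            class = "sim_config")
}

#' Simulate panel genotypes under Hardy-Weinberg equilibrium
#'
#' Draws risk-allele dosages Binomial(2, p) per variant, with case
#' frequencies for the \code{"t1d"} group and control frequencies for
#' \code{"control_like_monogenic"} (the study premise: monogenic children
#' carry the background-population risk-allele load).
#'
#' @param config A [sim_config()].
#' @param group \code{"t1d"} or \code{"control_like_monogenic"}.
#' @param n Number of subjects (defaults to the group size in the config).
#' @param seed Seed (defaults to a subsystem seed derived from the config).
#' @param id_prefix Prefix for generated subject ids.
#' @return A [cohort_genotypes] with no missing calls.
#' @export
simulate_genotypes <- function(config, group = c("t1d", "control_like_monogenic"),
                               n = NULL, seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  group <- match.arg(group)
  p <- if (group == "t1d") config$p1 else config$p0
  if (is.null(n)) n <- if (group == "t1d") config$n_t1d else config$n_monogenic
  if (is.null(seed)) seed <- .sub_seed(config$seed, if (group == "t1d") 1L else 2L)
  if (is.null(id_prefix)) id_prefix <- if (group == "t1d") "T1D" else "MONO"
  d <- .with_seed(seed, {
    vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
  })
  d <- matrix(as.integer(d), nrow = n, ncol = length(p))
  colnames(d) <- config$panel$variant_id
  ids <- sprintf("%s%03d", id_prefix, seq_len(n))
  cohort_genotypes(ids, d, matrix(FALSE, n, length(p)))
}

#' Simulate islet autoantibody titres
#'
#' Type 1 diabetes subjects get positivity indicators from the shared
#' latent-factor probit model of [calibrate_antibody_loading()]; titres are
#' then drawn from a sub-threshold component (negative calls) or a
#' supra-threshold component (positive calls), anchored at each assay's
#' positivity cut-off. Monogenic subjects draw from the negative component
#' only and are therefore always antibody-negative.
#'
#' @param config A [sim_config()].
#' @param groups Character vector, one of \code{"t1d"}/\code{"monogenic"}
#'   per subject.
#' @param seed Seed (default: config-derived).
#' @return Data.frame with \code{gad}, \code{ia2}, \code{znt8} titres (U/ml).
#' @export
simulate_antibodies <- function(config, groups, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- .sub_seed(config$seed, 3L)
  n <- length(groups)
  lam <- config$antibody_loading
  cuts <- stats::qnorm(1 - config$antibody_rates)
  thr <- unlist(config$thresholds[.assays])
  .with_seed(seed, {
    z <- stats::rnorm(n)
    out <- matrix(NA_real_, n, 3L, dimnames = list(NULL, .assays))
    for (a in 1:3) {
      u <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
      pos <- (u > cuts[a]) & groups == "t1d"
      neg_titre <- thr[a] * stats::rbeta(n, 2, 5)
      pos_titre <- thr[a] * (1 + stats::rgamma(n, shape = 1.5, rate = 1.5))
      out[, a] <- ifelse(pos, pos_titre, neg_titre)
    }
    as.data.frame(out)
  })
}

#' Simulate runs of homozygosity and the dense genotype overlay
#'
#' For each subject, plants true ROH segments (long for consanguineous
#' subjects, short and sporadic for outbred ones) on an evenly spaced dense
#' marker panel and generates per-marker heterozygosity calls: background
#' \code{het_rate} outside segments, residual \code{roh_err} inside.
#'
#' @param config A [sim_config()].
#' @param consanguineous Logical: simulate a consanguineous subject.
#' @param seed Seed.
#' @return List with \code{truth} (data.frame of planted segments:
#'   chrom/start/end/length_bp) and \code{calls} (marker table suitable for
#'   [detect_roh()]).
#' @export
simulate_roh <- function(config, consanguineous, seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    if (consanguineous) {
      n_seg <- stats::rpois(1, config$consang_n_seg)
      lens <- stats::rgamma(n_seg, shape = config$consang_len_shape,
                            scale = config$consang_len_scale)
    } else {
      n_seg <- stats::rpois(1, config$outbred_n_seg)
      lens <- stats::rgamma(n_seg, shape = config$outbred_len_shape,
                            scale = config$outbred_len_scale)
    }
    lens <- pmax(round(lens), config$marker_spacing_bp)
    if (any(lens > config$chrom_size_bp)) {
      stop("simulated segment longer than a chromosome; ",
           "reduce the segment length scale or enlarge the genome")
    }
    chrom_n <- ceiling(config$chrom_size_bp / config$marker_spacing_bp)
    pos1 <- seq(config$marker_spacing_bp, by = config$marker_spacing_bp,
                length.out = chrom_n)

    truth <- NULL
    if (n_seg > 0) {
      seg_chrom <- sample.int(config$n_chrom, n_seg, replace = TRUE)
      start <- round(stats::runif(n_seg, 1, config$chrom_size_bp - lens))
      truth <- data.frame(chrom = paste0("chr", seg_chrom),
                          start = start, end = start + lens - 1,
                          length_bp = lens, stringsAsFactors = FALSE)
      truth <- truth[order(seg_chrom, start), , drop = FALSE]
    }

    calls <- lapply(seq_len(config$n_chrom), function(ci) {
      ch <- paste0("chr", ci)
      in_roh <- rep(FALSE, chrom_n)
      if (!is.null(truth)) {
        tr <- truth[truth$chrom == ch, , drop = FALSE]
        for (k in seq_len(nrow(tr))) {
          in_roh <- in_roh | (pos1 >= tr$start[k] & pos1 <= tr$end[k])
        }
      }
      p_het <- ifelse(in_roh, config$roh_err, config$het_rate)
      data.frame(chrom = ch, pos = pos1,
                 is_het = stats::runif(chrom_n) < p_het,
                 is_missing = FALSE, stringsAsFactors = FALSE)
    })
    list(truth = if (is.null(truth)) {
           data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_bp = numeric())
         } else truth,
         calls = do.call(rbind, calls))
  })
}

#' Generate a complete synthetic screening cohort
#'
#' Builds, from a single seeded configuration, everything the pipeline
#' consumes: panel genotypes with their true GRS, antibody titres,
#' consanguinity assignments and (optionally) per-subject dense genotypes
#' with planted ROH segments. Monogenic subjects are listed first.
#'
#' @param config A [sim_config()].
#' @param include_roh Generate the dense ROH overlay (the slowest part;
#'   default TRUE).
#' @return An object of class \code{synthetic_cohort}: list with
#'   \code{subjects} (data.frame: subject_id, group, consanguineous_truth,
#'   titres, true_grs), \code{genotypes} ([cohort_genotypes]), \code{roh}
#'   (named per-subject list from [simulate_roh()], or NULL) and
#'   \code{config}.
#' @export
simulate_cohort <- function(config, include_roh = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  g_mono <- simulate_genotypes(config, "control_like_monogenic")
  g_t1d <- simulate_genotypes(config, "t1d")
  geno <- cohort_genotypes(
    c(g_mono$subject_ids, g_t1d$subject_ids),
    rbind(g_mono$dosage, g_t1d$dosage),
    rbind(g_mono$missing_mask, g_t1d$missing_mask))
  groups <- c(rep("monogenic", config$n_monogenic), rep("t1d", config$n_t1d))
  n <- length(groups)

  titres <- simulate_antibodies(config, groups)
  consang <- .with_seed(.sub_seed(config$seed, 4L), {
    stats::runif(n) < config$consanguinity_fraction
  })
  w <- config$panel$weight[match(colnames(geno$dosage), config$panel$variant_id)]
  true_grs <- as.vector(geno$dosage %*% w)

  roh <- NULL
  if (include_roh) {
    roh <- lapply(seq_len(n), function(j) {
      simulate_roh(config, consang[j], seed = .sub_seed(config$seed, 10L + j))
    })
    names(roh) <- geno$subject_ids
  }
  subjects <- data.frame(subject_id = geno$subject_ids,
                         group = groups,
                         consanguineous_truth = consang,
                         gad = titres$gad, ia2 = titres$ia2, znt8 = titres$znt8,
                         true_grs = true_grs,
                         stringsAsFactors = FALSE)
  structure(list(subjects = subjects, genotypes = geno, roh = roh,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$subjects), "subjects (",
      sum(x$subjects$group == "monogenic"), "monogenic,",
      sum(x$subjects$group == "t1d"), "T1D ), seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the files a real analysis would start from: a VCF 4.2 with the
#' nine panel genotypes (REF/ALT orientation alternates between variants so
#' both allele-matching paths are exercised on re-reading), a subject TSV
#' (group, titres, consanguinity truth) and a truth JSON holding the dosage
#' matrix, true scores and the generator seed. Re-reading the VCF through
#' [dosages_from_vcf()] reproduces the truth dosage matrix exactly.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths: \code{vcf}, \code{subjects},
#'   \code{truth}.
#' @export
emit_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel <- cohort$config$panel
  geno <- cohort$genotypes
  vcf_path <- file.path(dir, "cohort.vcf")
  subj_path <- file.path(dir, "subjects.tsv")
  truth_path <- file.path(dir, "truth.json")

  n_var <- nrow(panel)
  risk_is_alt <- seq_len(n_var) %% 2L == 1L  # alternate orientation
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=monoscreen_synthetic_cohort seed=%d",
                      cohort$config$seed),
              sprintf("##contig=<ID=%s>", unique(panel$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$subject_ids), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_var), function(i) {
    ref <- if (risk_is_alt[i]) panel$other_allele[i] else panel$risk_allele[i]
    alt <- if (risk_is_alt[i]) panel$risk_allele[i] else panel$other_allele[i]
    d <- geno$dosage[, i]
    alt_count <- if (risk_is_alt[i]) d else 2L - d
    paste(c(panel$chrom[i], panel$pos[i], panel$variant_id[i], ref, alt,
            ".", "PASS", ".", "GT", gt_codes[alt_count + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)

  utils::write.table(cohort$subjects, subj_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         subject_ids = geno$subject_ids,
         variant_ids = panel$variant_id,
         group = cohort$subjects$group,
         dosage = unname(geno$dosage),
         true_grs = cohort$subjects$true_grs,
         consanguineous_truth = cohort$subjects$consanguineous_truth),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(vcf = vcf_path, subjects = subj_path, truth = truth_path)
}
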