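#' Simulation configuration for synthetic cohorts
#'
#' Defines a cohort with the structure the M2EFM method assumes: a subset of
#' differentially methylated probes drives the expression of paired genes,
#' and a subset of those genes (plus age and stage) drives a censored
#' survival outcome and a binary response.
#'
#' @param n_samples Cohort size (default 300).
#' @param n_probes Total methylation probes (default 500, of which
#'   `n_m2eqtl` are planted).
#' @param n_genes Total genes (default 500).
#' @param n_m2eqtl Planted probe-gene pairs (default 20).
#' @param meth_effect Expression change per unit beta for planted pairs
#'   (default 1.5).
#' @param noise_sd Residual expression noise sd (default 0.5).
#' @param n_prognostic_genes Planted genes whose expression enters the
#'   hazard (default 10; taken from the planted m2eGenes first).
#' @param log_hazard_per_sd Log hazard ratio per standard deviation of each
#'   prognostic gene's expression (default 0.5).
#' @param age_effect Log hazard ratio per year of age, centered (default 0.02).
#' @param stage_effect Log hazard ratio for stage III/IV disease (default 0.5).
#' @param censoring_rate Target fraction of right-censored samples in
#'   `[0, 1)` (default 0.3); independent exponential censoring is calibrated
#'   to it.
#' @param baseline_hazard Baseline event rate (default 0.05 per time unit).
#' @param weibull_shape Event-time shape; 1 (default) gives exponential
#'   survival.
#' @param response_intercept,response_slope Logistic model for the binary
#'   response: `P(label) = plogis(intercept + slope * lp)` (defaults -1, 1).
#' @param seed Seed making the cohort fully reproducible (required).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_samples = 300, n_probes = 500, n_genes = 500,
                              n_m2eqtl = 20, meth_effect = 1.5, noise_sd = 0.5,
                              n_prognostic_genes = 10, log_hazard_per_sd = 0.5,
                              age_effect = 0.02, stage_effect = 0.5,
                              censoring_rate = 0.3, baseline_hazard = 0.05,
                              weibull_shape = 1,
                              response_intercept = -1, response_slope = 1,
                              seed = 1) {
  stopifnot(n_m2eqtl <= min(n_probes, n_genes),
            censoring_rate >= 0, censoring_rate < 1,
            n_samples >= 10, baseline_hazard > 0, weibull_shape > 0)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a multi-omic cohort with ground truth
#'
#' Generates methylation (beta values), expression, genomic annotation,
#' clinical covariates, a censored survival outcome and a binary response.
#' Null probes draw from Beta(2, 2); planted probes are bimodal across
#' samples (Beta(8, 2) / Beta(2, 8) halves). A planted gene's expression is
#' `5 + meth_effect * beta + Normal(0, noise_sd)`; null genes are pure
#' noise. Event times follow a Weibull (exponential by default) hazard
#' proportional to `exp(lp)` where `lp` sums the prognostic-gene and
#' clinical terms; censoring is independent exponential, calibrated to the
#' target censoring fraction. Annotation places each planted probe 5 kb from
#' its gene (cis) and null probes on a gene-free chromosome.
#'
#' @param config A [simulation_config()].
#' @return List with `meth`, `expr` ([omics_matrix()]), `annotation`,
#'   `clinical`, `survival` ([survival_outcome()]), `binary`
#'   ([binary_outcome()]) and `truth` (planted pairs, prognostic genes and
#'   coefficients, per-sample linear predictor).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  probes <- sprintf("cg%05d", seq_len(cf$n_probes))
  genes <- sprintf("GENE%04d", seq_len(cf$n_genes))

  # clinical covariates (breast-cohort-like demographics)
  age <- pmin(pmax(stats::rnorm(n, 58, 12), 25), 90)
  stage_raw <- sample(c("Stage I", "Stage IIA", "Stage IIB", "Stage IIIA",
                        "Stage IIIB", "Stage IV"),
                      n, replace = TRUE,
                      prob = c(0.18, 0.30, 0.22, 0.15, 0.10, 0.05))
  er <- sample(c("positive", "negative"), n, TRUE, prob = c(0.75, 0.25))
  pr <- sample(c("positive", "negative"), n, TRUE, prob = c(0.65, 0.35))
  her2 <- sample(c("positive", "negative"), n, TRUE, prob = c(0.2, 0.8))
  node <- sample(c("negative", "positive"), n, TRUE, prob = c(0.55, 0.45))
  clinical <- data.frame(sample_id = samples, age_at_diagnosis = age,
                         ajcc_stage = stage_raw, er_status = er,
                         pr_status = pr, her2_status = her2,
                         node_status = node, stringsAsFactors = FALSE)
  class(clinical) <- c("clinical_table", "data.frame")

  # methylation: planted probes bimodal, null probes Beta(2, 2)
  meth <- matrix(stats::rbeta(cf$n_probes * n, 2, 2), nrow = cf$n_probes,
                 dimnames = list(probes, samples))
  planted_probes <- probes[seq_len(cf$n_m2eqtl)]
  for (i in seq_len(cf$n_m2eqtl)) {
    high <- stats::rbinom(n, 1, 0.5) == 1
    meth[i, ] <- ifelse(high, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  }

  # expression: planted genes driven by their probe, null genes pure noise
  expr <- matrix(5 + stats::rnorm(cf$n_genes * n, 0, 1), nrow = cf$n_genes,
                 dimnames = list(genes, samples))
  planted_genes <- genes[seq_len(cf$n_m2eqtl)]
  for (i in seq_len(cf$n_m2eqtl)) {
    expr[i, ] <- 5 + cf$meth_effect * meth[i, ] +
      stats::rnorm(n, 0, cf$noise_sd)
  }

  # hazard: prognostic genes (planted m2eGenes first) + clinical terms
  n_prog <- cf$n_prognostic_genes
  prognostic <- utils::head(c(planted_genes,
                              setdiff(genes, planted_genes)), n_prog)
  lp <- rep(0, n)
  for (g in prognostic)
    lp <- lp + cf$log_hazard_per_sd * as.numeric(scale(expr[g, ]))
  stage3 <- collapse_stage(stage_raw) %in% c("III", "IV")
  lp <- lp + cf$age_effect * (age - mean(age)) + cf$stage_effect * stage3

  rate <- cf$baseline_hazard * exp(lp)
  u <- stats::runif(n)
  event_time <- (-log(u) / rate)^(1 / cf$weibull_shape)
  if (cf$censoring_rate > 0) {
    # exponential censoring rate solved so the expected censored fraction,
    # given the drawn event times, equals the target
    frac <- function(logc) mean(1 - exp(-exp(logc) * event_time)) -
      cf$censoring_rate
    root <- tryCatch(stats::uniroot(frac, c(-30, 30))$root,
                     error = function(e)
                       stop("censoring calibration infeasible for this configuration"))
    cens_time <- stats::rexp(n, exp(root))
    event <- event_time <= cens_time
    time <- pmin(event_time, cens_time)
  } else {
    event <- rep(TRUE, n)
    time <- event_time
  }
  surv <- survival_outcome(samples, time, event)
  label <- stats::rbinom(n, 1, stats::plogis(
    cf$response_intercept + cf$response_slope * lp)) == 1
  binary <- binary_outcome(samples, label)

  # annotation: genes 3 Mb apart on chr1..chr22; planted probes 5 kb from
  # their gene (cis); null probes on a gene-free chromosome
  gene_chrom <- paste0("chr", (seq_len(cf$n_genes) - 1) %% 22 + 1)
  gene_pos <- 1e6 + ((seq_len(cf$n_genes) - 1) %/% 22) * 3e6
  probe_chrom <- rep("chr23", cf$n_probes)
  probe_pos <- 1e6 + seq_len(cf$n_probes) * 1000
  nearest <- rep("", cf$n_probes)
  probe_chrom[seq_len(cf$n_m2eqtl)] <- gene_chrom[seq_len(cf$n_m2eqtl)]
  probe_pos[seq_len(cf$n_m2eqtl)] <- gene_pos[seq_len(cf$n_m2eqtl)] + 5000
  nearest[seq_len(cf$n_m2eqtl)] <- planted_genes
  annotation <- data.frame(
    feature_id = c(probes, genes),
    chrom = c(probe_chrom, gene_chrom),
    position = as.integer(c(probe_pos, gene_pos)),
    nearest_gene = c(nearest, rep("", cf$n_genes)),
    stringsAsFactors = FALSE)

  truth <- list(
    pairs = data.frame(probe_id = planted_probes, gene_id = planted_genes,
                       slope = rep(cf$meth_effect, cf$n_m2eqtl),
                       stringsAsFactors = FALSE),
    prognostic_genes = prognostic,
    log_hazard_per_sd = cf$log_hazard_per_sd,
    clinical_coefficients = c(age = cf$age_effect, stage3 = cf$stage_effect),
    linear_predictor = stats::setNames(lp, samples))

  list(meth = omics_matrix(meth, "methylation_beta"),
       expr = omics_matrix(expr, "expression"),
       annotation = annotation, clinical = clinical,
       survival = surv, binary = binary, truth = truth,
       config = cf)
}

#' Named benchmark configurations
#'
#' Fixed-seed simulation configs used throughout the test suite: a global
#' null (no planted effects), weak and strong signal at the default cohort
#' size, and small/large strong-signal cohorts.
#'
#' @return Named list of [simulation_config()] objects.
#' @export
default_benchmark_suite <- function() {
  list(
    null = simulation_config(meth_effect = 0, log_hazard_per_sd = 0,
                             age_effect = 0, stage_effect = 0, seed = 101),
    weak = simulation_config(meth_effect = 0.75, log_hazard_per_sd = 0.2,
                             seed = 202),
    strong = simulation_config(n_samples = 400, meth_effect = 1.5,
                               noise_sd = 0.5, log_hazard_per_sd = 0.5,
                               seed = 303),
    strong_small = simulation_config(n_samples = 150, seed = 404),
    strong_large = simulation_config(n_samples = 800, seed = 505))
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits the same formats the readers consume (`meth.tsv`, `expr.tsv`,
#' `annotation.tsv`, `clinical.tsv`, `survival.tsv`, `binary.tsv`) plus
#' `truth.json`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$meth, file.path(dir, "meth.tsv"))
  write_matrix(cohort$expr, file.path(dir, "expr.tsv"))
  utils::write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = cohort$survival$sample_ids,
               time = cohort$survival$time,
               event = as.integer(cohort$survival$event)),
    file.path(dir, "survival.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = cohort$binary$sample_ids,
               label = as.integer(cohort$binary$label)),
    file.path(dir, "binary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
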