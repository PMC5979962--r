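#' Quartile risk-group cutoffs
#'
#' The 25th and 75th percentiles (linear interpolation, type-7 convention by
#' default) of the training risk scores, defining the low/medium/high risk
#' groups.
#'
#' @param train_scores Numeric training risk scores.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 7).
#' @return Numeric vector `c(c25, c75)`.
#' @export
risk_group_cutoffs <- function(train_scores, type = 7) {
  q <- stats::quantile(train_scores, c(0.25, 0.75), type = type, names = FALSE)
  stats::setNames(q, c("c25", "c75"))
}

#' Assign samples to risk groups
#'
#' Low risk below the 25th-percentile cutoff, high risk above the
#' 75th-percentile cutoff, medium risk in between (both boundaries closed
#' into medium).
#'
#' @param scores Named numeric risk scores.
#' @param cutoffs `c(c25, c75)` from [risk_group_cutoffs()] on the training
#'   scores.
#' @return Factor with levels `low`, `medium`, `high`, named by sample.
#' @export
assign_risk_groups <- function(scores, cutoffs) {
  stopifnot(length(cutoffs) == 2, all(is.finite(cutoffs)),
            cutoffs[1] <= cutoffs[2])
  g <- ifelse(scores < cutoffs[1], "low",
              ifelse(scores > cutoffs[2], "high", "medium"))
  f <- factor(g, levels = c("low", "medium", "high"))
  names(f) <- names(scores)
  f
}

#' Hazard ratios between risk groups
#'
#' Unpenalized proportional-hazards fit of the outcome on risk-group
#' indicators (reference = low), with Wald 95% confidence intervals —
#' medium vs low and high vs low.
#'
#' @param groups Factor from [assign_risk_groups()].
#' @param outcome A [survival_outcome()] in the same sample order.
#' @return Data frame with columns `comparison`, `hr`, `lower95`, `upper95`,
#'   `p_value`. Groups without samples are omitted; groups without events
#'   trigger a warning (unbounded CI).
#' @export
group_hazard_ratios <- function(groups, outcome) {
  stopifnot(length(groups) == length(outcome$time))
  present <- levels(groups)[levels(groups) %in% unique(as.character(groups))]
  if (!"low" %in% present) stop("reference (low) group is empty")
  if (sum(outcome$event[groups == "low"]) < 1)
    stop("reference (low) group has no events")
  g <- factor(as.character(groups), levels = present)
  for (lev in setdiff(present, "low"))
    if (sum(outcome$event[g == lev]) == 0)
      warning("group '", lev, "' has zero events; its CI is unbounded")
  fit <- survival::coxph(
    survival::Surv(outcome$time, outcome$event) ~ g, ties = "breslow")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  data.frame(
    comparison = paste(sub("^g", "", names(cf)), "vs low"),
    hr = exp(unname(cf)),
    lower95 = exp(unname(cf) - 1.96 * se),
    upper95 = exp(unname(cf) + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(unname(cf) / se)),
    row.names = NULL)
}

#' Train/test split scheme for repeated evaluation
#'
#' @param n_repeats Number of random splits (default 100).
#' @param train_fraction Fraction of samples used for training (default 0.7;
#'   each training set has `floor(train_fraction * n)` samples).
#' @param master_seed Seed from which each repeat's split seed derives.
#' @param stratify Stratify splits by event/label so both halves contain
#'   events (default `TRUE`).
#' @return A `split_scheme` object.
#' @export
split_scheme <- function(n_repeats = 100, train_fraction = 0.7,
                         master_seed = 1, stratify = TRUE) {
  stopifnot(n_repeats >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 master_seed = as.integer(master_seed),
                 stratify = stratify),
            class = "split_scheme")
}

# one stratified train/test partition; returns indices into sample order
draw_split <- function(strata, train_fraction, seed) {
  set.seed(seed)
  n <- length(strata)
  n_train <- floor(train_fraction * n)
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- floor(train_fraction * length(idx))
    train <- c(train, sample(idx, k))
  }
  # top up to exactly floor(train_fraction * n) from the remaining pool
  pool <- setdiff(seq_len(n), train)
  if (length(train) < n_train)
    train <- c(train, sample(pool, n_train - length(train)))
  sort(train)
}

#' Run the repeated-split evaluation harness
#'
#' For each repeat, partitions the cohort into training and test sets (split
#' seed derived from the master seed and repeat index, stratified by the
#' event/label indicator), fits every model specification on the identical
#' training set — feature discovery and clinical covariate selection re-run
#' inside the training set only — and records the held-out metric (C-index
#' for survival outcomes, ROC AUC for binary) on the identical test set.
#' A model failing on a split records `NA` and the run continues.
#'
#' @param cohort A cohort bundle: list with elements `meth` (optional),
#'   `expr`, `annotation`, `clinical`, `outcome`, and optionally
#'   `candidate_probes`. All matrices must share one sample order (see
#'   [align_samples()]).
#' @param model_specs Named list of model specifications (see
#'   [spec_m2efm()], [spec_clinical_only()], [spec_cox_ridge()]).
#' @param scheme A [split_scheme()].
#' @return An `m2efm_eval_report`: list with `metrics` (data frame
#'   model/repeat/value), `summary` (median per model) and the scheme.
#' @export
run_split_harness <- function(cohort, model_specs, scheme = split_scheme()) {
  stopifnot(inherits(scheme, "split_scheme"), length(model_specs) >= 1)
  if (is.null(names(model_specs)) || any(!nzchar(names(model_specs))))
    stop("model_specs must be a named list")
  outcome <- cohort$outcome
  ids <- outcome$sample_ids
  strata <- if (scheme$stratify) {
    if (inherits(outcome, "survival_outcome")) outcome$event else outcome$label
  } else rep(1L, length(ids))
  rows <- list()
  for (r in seq_len(scheme$n_repeats)) {
    seed_r <- scheme$master_seed + r
    train_idx <- draw_split(strata, scheme$train_fraction, seed_r)
    train_ids <- ids[train_idx]
    test_ids <- ids[-train_idx]
    test_out <- subset_outcome(outcome, test_ids)
    for (nm in names(model_specs)) {
      value <- tryCatch({
        predictor <- model_specs[[nm]]$fit(cohort, train_ids, seed = seed_r)
        risk <- predictor(cohort, test_ids)
        if (inherits(outcome, "survival_outcome"))
          concordance_index(risk, test_out)
        else
          auc_binary(risk, test_out)
      }, error = function(e) {
        message(sprintf("harness: model '%s' failed on repeat %d: %s",
                        nm, r, conditionMessage(e)))
        NA_real_
      })
      rows[[length(rows) + 1]] <- data.frame(
        model = nm, split = r, value = value, stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  summary <- stats::aggregate(value ~ model, data = metrics,
                              FUN = stats::median, na.action = stats::na.omit)
  colnames(summary) <- c("model", "median")
  structure(list(metrics = metrics, summary = summary, scheme = scheme),
            class = "m2efm_eval_report")
}

#' @export
print.m2efm_eval_report <- function(x, ...) {
  cat(sprintf("m2efm_eval_report: %d repeats\n", x$scheme$n_repeats))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Compare two models across paired splits
#'
#' Two-tailed Wilcoxon signed-rank test on the per-split metric values of
#' two models from the same harness run; splits where either model failed
#' are excluded pairwise (with a message).
#'
#' @param report An `m2efm_eval_report`.
#' @param model_a,model_b Model names in the report.
#' @return List with `median_a`, `median_b`, `n_pairs` and `p_value`.
#' @export
compare_models <- function(report, model_a, model_b) {
  m <- report$metrics
  a <- m$value[m$model == model_a][order(m$split[m$model == model_a])]
  b <- m$value[m$model == model_b][order(m$split[m$model == model_b])]
  if (!length(a) || !length(b)) stop("model not found in report")
  ok <- stats::complete.cases(a, b)
  if (any(!ok))
    message(sprintf("compare_models: %d split(s) excluded pairwise (failures)",
                    sum(!ok)))
  w <- wilcoxon_signed_rank(a[ok], b[ok])
  list(median_a = stats::median(a[ok]), median_b = stats::median(b[ok]),
       n_pairs = sum(ok), p_value = w$p_value)
}

# IPCW cumulative-case / dynamic-control sensitivity & specificity at horizon
cd_roc_rates <- function(risk, outcome, horizon, cutoff) {
  G <- censoring_km(outcome)
  g_event <- km_step_eval(G$times, G$surv, outcome$time, left = TRUE)
  g_h <- km_step_eval(G$times, G$surv, horizon)
  case_w <- ifelse(outcome$time <= horizon & outcome$event, 1 / g_event, 0)
  ctrl <- outcome$time > horizon
  sens <- if (sum(case_w) > 0) sum(case_w[risk > cutoff]) / sum(case_w) else NA
  spec <- if (any(ctrl)) sum(ctrl & risk <= cutoff) / sum(ctrl) else NA
  c(sens = sens, spec = spec)
}

#' Predictive values at a time horizon
#'
#' Determines the risk-score cutoff that equalizes time-dependent
#' sensitivity and specificity (cumulative-case / dynamic-control ROC with
#' inverse-probability-of-censoring weights) at the horizon on the training
#' set, then applies it to the test set to obtain PPV and NPV at the same
#' horizon with the same estimator. Raw classification counts (over test
#' samples whose event status at the horizon is known) are also returned.
#'
#' @param train_risk,train_outcome Training risk scores and
#'   [survival_outcome()].
#' @param test_risk,test_outcome Test risk scores and outcome.
#' @param horizon Time point within the follow-up of both sets.
#' @return List: `cutoff`, `ppv`, `npv` (IPCW estimates), and raw counts
#'   `predicted_negative`, `true_negative`, `predicted_positive`,
#'   `true_positive`.
#' @export
npv_ppv_at_horizon <- function(train_risk, train_outcome,
                               test_risk, test_outcome, horizon) {
  if (horizon > max(train_outcome$time) || horizon > max(test_outcome$time))
    stop("horizon beyond follow-up range")
  if (!any(train_outcome$time <= horizon & train_outcome$event))
    stop("no training events before the horizon")
  cand <- sort(unique(train_risk))
  gaps <- vapply(cand, function(c) {
    r <- cd_roc_rates(train_risk, train_outcome, horizon, c)
    abs(r["sens"] - r["spec"])
  }, numeric(1))
  cutoff <- cand[which.min(gaps)]

  G <- censoring_km(test_outcome)
  g_event <- km_step_eval(G$times, G$surv, test_outcome$time, left = TRUE)
  g_h <- km_step_eval(G$times, G$surv, horizon)
  case_w <- ifelse(test_outcome$time <= horizon & test_outcome$event,
                   1 / g_event, 0)
  ctrl_w <- ifelse(test_outcome$time > horizon, 1 / g_h, 0)
  pos <- test_risk > cutoff
  ppv <- sum(case_w[pos]) / (sum(case_w[pos]) + sum(ctrl_w[pos]))
  npv <- sum(ctrl_w[!pos]) / (sum(case_w[!pos]) + sum(ctrl_w[!pos]))

  known_case <- test_outcome$time <= horizon & test_outcome$event
  known_ctrl <- test_outcome$time > horizon
  known <- known_case | known_ctrl
  list(cutoff = cutoff, ppv = unname(ppv), npv = unname(npv),
       predicted_negative = sum(!pos & known),
       true_negative = sum(!pos & known_ctrl),
       predicted_positive = sum(pos & known),
       true_positive = sum(pos & known_case))
}

#' Infer receptor status from marker expression
#'
#' Clusters samples on receptor-associated expression probes with a
#' two-component Gaussian mixture (fit by expectation-maximization on the
#' first principal component when several probes are given); the component
#' with the higher mean is called positive.
#'
#' @param expr [omics_matrix()] restricted to the marker probes for one
#'   receptor (>= 20 samples).
#' @param min_separation Warn when the absolute mean difference is below
#'   this many pooled standard deviations (default 2).
#' @return Data frame with `sample_id`, `status` ("positive"/"negative") and
#'   `posterior` (posterior probability of the assigned component).
#' @importFrom mclust Mclust mclustBIC
#' @export
infer_receptor_status <- function(expr, min_separation = 2) {
  stopifnot(inherits(expr, "omics_matrix"))
  if (length(expr$sample_ids) < 20)
    stop("at least 20 samples required for mixture fitting")
  x <- if (length(expr$feature_ids) > 1) {
    pc <- stats::prcomp(t(expr$values), center = TRUE, scale. = FALSE)$x[, 1]
    # orient the component so "higher = more marker expression"
    if (stats::cor(pc, colMeans(expr$values)) < 0) pc <- -pc
    pc
  } else as.numeric(expr$values[1, ])
  fit <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture model failed to converge")
  mu <- fit$parameters$mean
  pooled_sd <- sqrt(mean(fit$parameters$variance$sigmasq))
  if (abs(diff(mu)) < min_separation * pooled_sd)
    warning("component separation below threshold; receptor status unreliable")
  pos_comp <- which.max(mu)
  status <- ifelse(fit$classification == pos_comp, "positive", "negative")
  posterior <- fit$z[cbind(seq_along(x), fit$classification)]
  data.frame(sample_id = expr$sample_ids, status = status,
             posterior = posterior, stringsAsFactors = FALSE)
}
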