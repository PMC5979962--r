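# brute-force oracles, kept deliberately naive and separate from the
# implementations they check
cindex_oracle <- function(risk, time, event) {
  num <- den <- 0
  n <- length(risk)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    if (time[i] < time[j] && event[i]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("concordance matches hand-enumerated and oracle values", {
  expect_equal(concordance_index(c(3, 2, 1),
                                 list(time = c(1, 2, 3),
                                      event = c(TRUE, TRUE, TRUE))), 1.0)
  # 5 comparable pairs, 4 concordant
  expect_equal(concordance_index(c(0.8, 0.85, 0.5, 0.9),
                                 list(time = c(2, 4, 5, 1),
                                      event = c(1, 0, 1, 1) == 1)), 0.8)
  expect_error(concordance_index(c(1, 2), list(time = c(1, 2),
                                               event = c(FALSE, FALSE))),
               "no comparable pairs")
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    time <- sample(1:15, n, replace = TRUE) + runif(n) * (i %% 2)  # some ties
    event <- runif(n) < 0.7
    risk <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    if (!any(outer(time, time, `<`) & event)) next
    expect_identical(concordance_index(risk, list(time = time, event = event)),
                     cindex_oracle(risk, time, event))
  }
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  expect_equal(auc_binary(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0) == 1), 0.75)
  expect_equal(auc_binary(c(5, 4, 2, 1), c(1, 1, 0, 0) == 1), 1.0)
  expect_equal(auc_binary(rep(0.5, 6), c(1, 1, 1, 0, 0, 0) == 1), 0.5)
  expect_error(auc_binary(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(32)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    labels <- runif(n) < 0.5
    if (all(labels) || !any(labels)) next
    expect_equal(auc_binary(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("Brier score fixtures: constant, oracle and hand-computed IPCW", {
  # constant S = 0.5 with no censoring: (1{T>t} - 0.5)^2 = 0.25 always
  out <- survival_outcome(paste0("s", 1:4), c(2, 4, 6, 8), rep(TRUE, 4))
  grid <- c(1, 3, 5, 7)
  sp <- matrix(0.5, 4, 4)
  expect_equal(integrated_brier_score(sp, out, grid), 0.25)
  # oracle step predictions score zero error
  sp_oracle <- t(vapply(out$time, function(ti) as.numeric(grid < ti),
                        numeric(4)))
  expect_equal(integrated_brier_score(sp_oracle, out, grid), 0)
  # censored 4-sample instance against by-hand IPCW arithmetic:
  # times (1+, 2, 3+, 4), censoring KM: G = 3/4 after t = 1, 3/8 after t = 3
  out_c <- survival_outcome(paste0("s", 1:4), 1:4,
                            c(FALSE, TRUE, FALSE, TRUE))
  sp_c <- matrix(c(0.9, 0.8, 0.7, 0.6), 4, 1)
  # at t = 2.5: s1 censored before -> weight 0; s2 event (G(2-) = 3/4);
  # s3, s4 still at risk (G(2.5) = 3/4); s2 contributes S^2, others (1-S)^2
  hand <- (0.8^2 / (3/4) + (1 - 0.7)^2 / (3/4) + (1 - 0.6)^2 / (3/4)) / 4
  expect_equal(integrated_brier_score(sp_c, out_c, 2.5), hand,
               tolerance = 1e-10)
  expect_error(integrated_brier_score(sp_c, out_c, 5), "beyond last follow-up")
})

test_that("risk-group assignment follows the quartile conventions", {
  scores <- setNames(seq(10, 80, 10), paste0("s", 1:8))
  cuts <- risk_group_cutoffs(scores)
  expect_equal(unname(cuts), c(27.5, 62.5))  # type-7 linear interpolation
  g <- assign_risk_groups(scores, cuts)
  expect_identical(names(scores)[g == "low"], c("s1", "s2"))
  expect_identical(names(scores)[g == "high"], c("s7", "s8"))
  # identical scores all fall in medium; boundary values are medium
  same <- setNames(rep(5, 4), paste0("t", 1:4))
  expect_true(all(assign_risk_groups(same, risk_group_cutoffs(same)) == "medium"))
  expect_identical(as.character(assign_risk_groups(
    setNames(62.5, "x"), cuts)), "medium")
})

test_that("Kaplan-Meier curves match product-limit hand calculations", {
  km <- km_curve(survival_outcome(paste0("s", 1:3), c(1, 2, 3), rep(TRUE, 3)))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  km_cens <- km_curve(survival_outcome(paste0("s", 1:3), c(1, 2, 3),
                                       rep(FALSE, 3)))
  expect_true(all(km_cens$survival == 1))
  # two tied events at t=2 among 4 at risk: single decrement to 0.5
  km_tie <- km_curve(survival_outcome(paste0("s", 1:4), c(2, 2, 3, 4),
                                      c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(km_tie$survival[km_tie$time == 2], 0.5)
})

test_that("risk groups order survival curves on strong-signal data", {
  ordered_ok <- 0L
  for (s in 1:10) {
    co <- simulate_cohort(simulation_config(
      n_samples = 300, n_probes = 30, n_genes = 30, n_m2eqtl = 10,
      n_prognostic_genes = 10, seed = 300 + s))
    risk <- setNames(exp(co$truth$linear_predictor), co$survival$sample_ids)
    g <- assign_risk_groups(risk, risk_group_cutoffs(risk))
    grid <- seq(1, quantile(co$survival$time, 0.6), length.out = 8)
    surv_at <- function(keep) {
      km <- km_curve(subset_outcome(co$survival,
                                    co$survival$sample_ids[keep]))
      vapply(grid, function(t) {
        i <- sum(km$time <= t); if (i == 0) 1 else km$survival[i]
      }, numeric(1))
    }
    s_low <- surv_at(g == "low"); s_med <- surv_at(g == "medium")
    s_high <- surv_at(g == "high")
    if (all(s_low >= s_med - 1e-12) && all(s_med >= s_high - 1e-12))
      ordered_ok <- ordered_ok + 1L
  }
  expect_gte(ordered_ok, 9L)
})

test_that("group hazard ratios recover planted and null effects", {
  set.seed(41)
  n <- 1000
  ids <- sprintf("s%04d", 1:n)
  g <- factor(rep(c("low", "high"), each = n / 2),
              levels = c("low", "medium", "high"))
  t_event <- rexp(n, 0.05 * ifelse(g == "high", 5, 1))
  out <- survival_outcome(ids, t_event, rep(TRUE, n))
  hr <- group_hazard_ratios(g, out)
  expect_equal(nrow(hr), 1)  # empty medium group omitted
  expect_gt(hr$hr, 4); expect_lt(hr$hr, 6)
  # two identical groups: HR near 1
  g2 <- factor(rep(c("low", "medium"), n / 2), levels = levels(g))
  t2 <- rexp(n, 0.05)
  hr2 <- group_hazard_ratios(g2, survival_outcome(ids, t2, rep(TRUE, n)))
  expect_gt(hr2$hr, 0.8); expect_lt(hr2$hr, 1.25)
})

test_that("signed-rank test matches exact enumeration and handles edge cases", {
  expect_warning(res <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res$p_value, 1)
  # all-positive differences, n = 6: exact two-tailed p = 2/2^6
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), rep(0, 6))$p_value,
               0.03125)
  # exhaustive enumeration oracle for n <= 12 untied differences
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- sample(setdiff(-20:20, 0), n)  # distinct magnitudes
    while (anyDuplicated(abs(d))) d <- sample(setdiff(-20:20, 0), n)
    got <- wilcoxon_signed_rank(d, rep(0, n))
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_exact <- min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
    expect_equal(got$p_value, p_exact)
  }
})

test_that("signed-rank rejection rate is calibrated under the null", {
  set.seed(43)
  rejections <- 0L
  for (i in 1:500) {
    a <- rnorm(100); b <- rnorm(100)
    if (wilcoxon_signed_rank(a, b)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / 500
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
})

test_that("the split harness is deterministic and sizes splits correctly", {
  co <- small_cohort(seed = 51, n = 100)
  bundle <- list(meth = co$meth, expr = co$expr, annotation = co$annotation,
                 clinical = co$clinical, outcome = co$survival)
  specs <- list(clin = spec_clinical_only())
  sch <- split_scheme(n_repeats = 3, master_seed = 17)
  r1 <- suppressMessages(run_split_harness(bundle, specs, sch))
  r2 <- suppressMessages(run_split_harness(bundle, specs, sch))
  expect_identical(r1$metrics, r2$metrics)
  # 70/30 split: training size floor(0.7 * n), via the internal splitter
  strata <- co$survival$event
  idx <- m2efm:::draw_split(strata, 0.7, seed = 99)
  expect_equal(length(idx), floor(0.7 * 100))
  # stratification puts events in both halves
  expect_gt(sum(strata[idx]), 0)
  expect_gt(sum(strata[-idx]), 0)
})

test_that("paired comparisons exclude failed splits pairwise", {
  rep <- structure(list(metrics = data.frame(
    model = rep(c("a", "b"), each = 4), split = rep(1:4, 2),
    value = c(0.8, 0.7, NA, 0.75, 0.6, 0.65, 0.62, 0.61)),
    summary = NULL, scheme = split_scheme(4)),
    class = "m2efm_eval_report")
  expect_message(out <- compare_models(rep, "a", "b"), "1 split")
  expect_equal(out$n_pairs, 3)
})

test_that("predictive values at a horizon: perfect and perturbed cases", {
  # uncensored, perfectly separating training risks
  tr_out <- survival_outcome(paste0("t", 1:8), c(1, 1.5, 2, 2.5, 9, 9, 9, 9),
                             c(rep(TRUE, 4), rep(FALSE, 4) | TRUE))
  tr_risk <- c(9, 8, 7, 6, 2, 1.5, 1.2, 1)
  te_out <- survival_outcome(paste0("u", 1:4), c(1, 2, 9, 9),
                             c(TRUE, TRUE, TRUE, TRUE))
  te_risk <- c(9, 8, 2, 1)
  res <- npv_ppv_at_horizon(tr_risk, tr_out, te_risk, te_out, horizon = 3)
  expect_equal(res$ppv, 1.0)
  expect_equal(res$npv, 1.0)
  expect_equal(res$predicted_negative, 2)
  expect_equal(res$true_negative, 2)
  expect_equal(res$predicted_positive, 2)
  expect_equal(res$true_positive, 2)
  # flipping one predicted-negative sample to an early event halves the NPV
  te_out2 <- survival_outcome(paste0("u", 1:4), c(1, 2, 2.5, 9), rep(TRUE, 4))
  res2 <- npv_ppv_at_horizon(tr_risk, tr_out, te_risk, te_out2, horizon = 3)
  expect_equal(res2$npv, 0.5)
  expect_error(npv_ppv_at_horizon(tr_risk, tr_out, te_risk, te_out, 99),
               "beyond follow-up")
})

test_that("the equal-sensitivity-specificity cutoff sits near the median under the null", {
  set.seed(44)
  n <- 400
  risk <- rnorm(n)
  out <- survival_outcome(sprintf("s%03d", 1:n), rexp(n, 0.2), rep(TRUE, n))
  res <- npv_ppv_at_horizon(risk, out, risk, out, horizon = 3)
  expect_lt(abs(res$cutoff - median(risk)), 0.35)
})

test_that("variance inflation factor follows 1 / (1 - R^2)", {
  set.seed(45)
  z <- matrix(rnorm(300), 100, 3)
  # response orthogonal to covariates in expectation; regress out to be exact
  y <- rnorm(100)
  y_orth <- residuals(lm(y ~ z))
  expect_equal(variance_inflation_factor(y_orth, z), 1.0, tolerance = 1e-10)
  # R^2 = 0.5 by construction: y = signal + noise with equal variances
  signal <- z[, 1]
  noise <- residuals(lm(rnorm(100) ~ z))
  noise <- noise * sd(signal) / sd(noise)
  y2 <- signal + noise
  r2 <- summary(lm(y2 ~ z))$r.squared
  expect_equal(variance_inflation_factor(y2, z), 1 / (1 - r2))
  expect_gt(variance_inflation_factor(y2, z), 1.8)
  expect_lt(variance_inflation_factor(y2, z), 2.3)
  # exact linear combination: R^2 = 1, VIF infinite
  expect_equal(variance_inflation_factor(z %*% c(1, 2, 3), z), Inf)
  expect_error(variance_inflation_factor(y, cbind(z, z[, 1])),
               "rank deficient")
})

test_that("receptor-status inference separates a clear bimodal mixture", {
  set.seed(46)
  n <- 200
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  vals <- matrix(rnorm(3 * n, ifelse(truth, 5, -5), 1), nrow = 3,
                 byrow = TRUE,
                 dimnames = list(paste0("probe", 1:3), sprintf("s%03d", 1:n)))
  expr <- omics_matrix(vals, "expression")
  res <- infer_receptor_status(expr)
  acc <- mean((res$status == "positive") == truth)
  expect_gte(acc, 0.99)
  expect_true(all(res$posterior >= 0.5))
  # labels invariant to affine rescaling of the expression values
  expr2 <- omics_matrix(vals * 3.7 + 11, "expression")
  expect_identical(infer_receptor_status(expr2)$status, res$status)
  # unimodal input warns about weak separation
  uni <- omics_matrix(matrix(rnorm(n, 0, 1), 1,
                             dimnames = list("probe1", sprintf("s%03d", 1:n))),
                      "expression")
  expect_warning(infer_receptor_status(uni), "separation")
})
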