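#' Harrell's concordance index
#'
#' Probability that, of a comparable pair of samples, the one with the higher
#' risk score has the event first. A pair is comparable when the smaller of
#' the two follow-up times ends in an observed event (pairs with tied times
#' are not comparable); tied risk scores count 1/2.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param outcome A [survival_outcome()] in the same sample order, or a list
#'   with `time` and `event`.
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(risk, outcome) {
  time <- outcome$time; event <- outcome$event
  stopifnot(length(risk) == length(time), length(time) == length(event))
  dt <- outer(time, time, `<`)              # [i,j]: t_i < t_j
  comparable <- dt & event                  # earlier member had the event
  if (!any(comparable)) stop("no comparable pairs (all censored or tied)")
  dr <- outer(risk, risk, `-`)              # risk_i - risk_j
  conc <- sum(comparable & dr > 0) + 0.5 * sum(comparable & dr == 0)
  conc / sum(comparable)
}

#' ROC area for a binary outcome
#'
#' Mann-Whitney AUC: the probability a random positive scores above a random
#' negative, with score ties counting 1/2 (computed from midranks).
#'
#' @param scores Numeric scores.
#' @param labels Logical/0-1 labels in the same order, or a
#'   [binary_outcome()].
#' @return AUC in \[0, 1\].
#' @export
auc_binary <- function(scores, labels) {
  if (inherits(labels, "binary_outcome")) labels <- labels$label
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# evaluate a Kaplan-Meier step function at times t (left limit if left=TRUE)
km_step_eval <- function(times, surv, t, left = FALSE) {
  vapply(t, function(tt) {
    idx <- if (left) sum(times < tt) else sum(times <= tt)
    if (idx == 0) 1 else surv[idx]
  }, numeric(1))
}

censoring_km <- function(outcome) {
  fit <- survival::survfit(survival::Surv(outcome$time, !outcome$event) ~ 1)
  list(times = fit$time, surv = fit$surv)
}

#' Integrated Brier score with censoring weights
#'
#' Prediction error of survival-probability forecasts: the Brier score at
#' each grid time, weighted by the inverse probability of censoring (IPCW;
#' censoring distribution estimated by Kaplan-Meier on the censoring
#' indicator), averaged over the grid by trapezoidal integration.
#'
#' @param surv_prob Numeric matrix of predicted survival probabilities,
#'   samples x grid times.
#' @param outcome A [survival_outcome()] in row order.
#' @param time_grid Increasing evaluation times within follow-up range.
#' @return Non-negative integrated Brier score (a single time returns the
#'   plain Brier score at that time).
#' @export
integrated_brier_score <- function(surv_prob, outcome, time_grid) {
  stopifnot(is.matrix(surv_prob), nrow(surv_prob) == length(outcome$time),
            ncol(surv_prob) == length(time_grid))
  if (is.unsorted(time_grid, strictly = TRUE)) stop("time_grid must be increasing")
  if (max(time_grid) > max(outcome$time))
    stop("time_grid extends beyond last follow-up time")
  G <- censoring_km(outcome)
  g_at_event <- km_step_eval(G$times, G$surv, outcome$time, left = TRUE)
  bs <- vapply(seq_along(time_grid), function(k) {
    t <- time_grid[k]
    g_t <- km_step_eval(G$times, G$surv, t)
    had_event <- outcome$time <= t & outcome$event
    at_risk <- outcome$time > t
    w_event <- ifelse(had_event, 1 / g_at_event, 0)
    w_risk <- ifelse(at_risk, 1 / g_t, 0)
    mean(surv_prob[, k]^2 * w_event + (1 - surv_prob[, k])^2 * w_risk)
  }, numeric(1))
  if (length(time_grid) == 1) return(bs)
  span <- diff(range(time_grid))
  sum(diff(time_grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / span
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for one group of samples; tied event times
#' decrement the curve in a single step.
#'
#' @param outcome A [survival_outcome()].
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (one row per distinct observed time).
#' @export
km_curve <- function(outcome) {
  stopifnot(length(outcome$time) >= 1)
  fit <- survival::survfit(survival::Surv(outcome$time, outcome$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-tailed Wilcoxon signed-rank test for paired metrics
#'
#' Zero differences are dropped (all-zero input returns p = 1 with a
#' warning). With 25 or fewer untied pairs the exact signed-rank null
#' distribution is used; otherwise a normal approximation with continuity
#' correction and a tie correction to the variance.
#'
#' @param a,b Paired numeric vectors.
#' @return List with `statistic` (sum of positive-difference ranks), `n`
#'   (non-zero pairs) and `p_value` (two-tailed).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  d <- (a - b)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(list(statistic = 0, n = 0L, p_value = 1))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    p <- 2 * min(stats::psignrank(w, n), 1 - stats::psignrank(w - 1, n))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = w, n = as.integer(n), p_value = min(p, 1))
}

#' Variance inflation factor of a response against covariates
#'
#' Regresses the response (e.g. the molecular risk score) on a covariate
#' design and reports `1 / (1 - R^2)`; values near 1 indicate the response
#' carries information independent of the covariates.
#'
#' @param response Numeric vector.
#' @param design Numeric matrix or data frame of covariates.
#' @return VIF (>= 1); infinite when the response is an exact linear
#'   combination of the covariates.
#' @export
variance_inflation_factor <- function(response, design) {
  design <- as.matrix(design)
  stopifnot(length(response) == nrow(design))
  if (qr(cbind(1, design))$rank < ncol(design) + 1)
    stop("covariate design is rank deficient")
  fit <- stats::lm(response ~ design)
  # summary.lm warns on an exact fit; R^2 = 1 (infinite VIF) is a valid answer
  r2 <- suppressWarnings(summary(fit)$r.squared)
  1 / (1 - r2)
}
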