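#' Model specifications for the evaluation harness
#'
#' A model specification is a named recipe the harness can fit on a training
#' split and apply to a test split. Each `fit(cohort, train_ids, seed)`
#' returns a predictor `function(cohort, ids)` yielding per-sample risk
#' scores.
#'
#' `spec_m2efm()` runs the full two-stage pipeline inside the training set:
#' m2eQTL association and feature selection, penalized (ridge) molecular
#' model, LASSO clinical covariate selection, and the unpenalized final
#' model. `mode = "full"` uses methylation betas plus m2eGene expression;
#' `mode = "expression_only"` substitutes each probe's cis gene
#' ([substitute_cis_genes()]) so the model transfers to cohorts without
#' methylation.
#'
#' @param mode `"full"` or `"expression_only"`.
#' @param q_threshold,max_probes,max_genes,cis_window Passed to
#'   [discover_feature_set()] / [associate()].
#' @param clinical Include the clinical stage (default `TRUE`).
#' @param candidates Clinical covariate names offered to the LASSO; default
#'   `c("age_at_diagnosis", "ajcc_stage")`.
#' @param nfolds Cross-validation folds for the penalized fits.
#' @return A model specification (list with `name` and `fit`).
#' @export
spec_m2efm <- function(mode = c("full", "expression_only"),
                       q_threshold = 0.05, max_probes = Inf, max_genes = Inf,
                       cis_window = 1e6, clinical = TRUE,
                       candidates = c("age_at_diagnosis", "ajcc_stage"),
                       nfolds = 10) {
  mode <- match.arg(mode)
  family_of <- function(outcome)
    if (inherits(outcome, "survival_outcome")) "proportional_hazards" else "logistic"
  fit <- function(cohort, train_ids, seed) {
    fam <- family_of(cohort$outcome)
    meth_tr <- subset_omics(cohort$meth, samples = train_ids)
    if (!is.null(cohort$candidate_probes))
      meth_tr <- subset_omics(meth_tr, features = intersect(
        cohort$candidate_probes, meth_tr$feature_ids))
    expr_tr <- subset_omics(cohort$expr, samples = train_ids)
    rec <- associate(meth_tr, expr_tr, cohort$annotation, cis_window = cis_window)
    fs <- discover_feature_set(rec, cohort$annotation,
                               q_threshold = q_threshold,
                               max_probes = max_probes, max_genes = max_genes,
                               cis_window = cis_window)
    features_for <- function(ids) {
      if (mode == "full")
        build_feature_matrix(fs,
                             subset_omics(cohort$meth, samples = ids),
                             subset_omics(cohort$expr, samples = ids))
      else
        substitute_cis_genes(fs, subset_omics(cohort$expr, samples = ids))
    }
    x_tr <- features_for(train_ids)
    mol <- fit_molecular_model(x_tr, cohort$outcome, fam,
                               nfolds = nfolds, seed = seed)
    risk_tr <- compute_risk_score(mol, x_tr)
    sel <- character(0)
    cl_tr <- NULL
    if (clinical && !is.null(cohort$clinical)) {
      cl_tr <- cohort$clinical[match(train_ids, cohort$clinical$sample_id), ,
                               drop = FALSE]
      sel <- suppressWarnings(select_clinical_covariates(
        cl_tr, cohort$outcome, candidates, fam, nfolds = nfolds, seed = seed))
    }
    final <- fit_final_model(risk_tr, cl_tr, cohort$outcome, fam,
                             covariates = sel)
    function(cohort, ids) {
      risk <- compute_risk_score(mol, features_for(ids))
      cl <- if (length(sel))
        cohort$clinical[match(ids, cohort$clinical$sample_id), , drop = FALSE]
      stats::predict(final, risk, cl)
    }
  }
  list(name = paste0("m2efm_", mode), fit = fit)
}

#' @rdname spec_m2efm
#' @export
spec_clinical_only <- function(candidates = c("age_at_diagnosis", "ajcc_stage"),
                               nfolds = 10) {
  fit <- function(cohort, train_ids, seed) {
    fam <- if (inherits(cohort$outcome, "survival_outcome"))
      "proportional_hazards" else "logistic"
    cl_tr <- cohort$clinical[match(train_ids, cohort$clinical$sample_id), ,
                             drop = FALSE]
    sel <- suppressWarnings(select_clinical_covariates(
      cl_tr, cohort$outcome, candidates, fam, nfolds = nfolds, seed = seed))
    if (!length(sel)) sel <- candidates  # degenerate selection: keep all
    enc <- encode_clinical(cl_tr, sel)
    out_tr <- subset_outcome(cohort$outcome, train_ids)
    df <- as.data.frame(enc$x)
    if (fam == "proportional_hazards") {
      .y <- survival::Surv(out_tr$time, out_tr$event)
      m <- survival::coxph(.y ~ ., data = df, ties = "breslow")
    } else {
      df$.y <- as.integer(out_tr$label)
      m <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    }
    function(cohort, ids) {
      cl <- cohort$clinical[match(ids, cohort$clinical$sample_id), , drop = FALSE]
      x <- encode_clinical(cl, sel, levels = enc$levels)$x
      cf <- stats::coef(m)
      terms <- setdiff(names(cf), "(Intercept)")
      lp <- drop(x[, terms, drop = FALSE] %*% cf[terms])
      stats::setNames(exp(lp), ids)
    }
  }
  list(name = "clinical_only", fit = fit)
}

#' @rdname spec_m2efm
#' @param mad_filter Probe truncation for the comparator (default: number of
#'   genes).
#' @param use_meth Include methylation probes in the comparator ridge fit.
#' @export
spec_cox_ridge <- function(use_meth = TRUE, mad_filter = NULL, clinical = TRUE,
                           candidates = c("age_at_diagnosis", "ajcc_stage"),
                           nfolds = 10) {
  fit <- function(cohort, train_ids, seed) {
    fam <- if (inherits(cohort$outcome, "survival_outcome"))
      "proportional_hazards" else "logistic"
    expr_tr <- subset_omics(cohort$expr, samples = train_ids)
    meth_tr <- if (use_meth && !is.null(cohort$meth))
      subset_omics(cohort$meth, samples = train_ids) else NULL
    cl_tr <- if (clinical && !is.null(cohort$clinical))
      cohort$clinical[match(train_ids, cohort$clinical$sample_id), , drop = FALSE]
    sel <- character(0)
    if (!is.null(cl_tr))
      sel <- suppressWarnings(select_clinical_covariates(
        cl_tr, cohort$outcome, candidates, fam, nfolds = nfolds, seed = seed))
    cmp <- fit_comparator_ridge(meth_tr, expr_tr, cl_tr, cohort$outcome, fam,
                                covariates = sel, mad_filter = mad_filter,
                                nfolds = nfolds, seed = seed)
    kept_probes <- setdiff(cmp$molecular$feature_ids, expr_tr$feature_ids)
    function(cohort, ids) {
      blocks <- list(t(subset_omics(cohort$expr, samples = ids)$values))
      if (length(kept_probes))
        blocks <- c(list(t(subset_omics(cohort$meth, features = kept_probes,
                                        samples = ids)$values)), blocks)
      x <- do.call(cbind, blocks)
      risk <- compute_risk_score(cmp$molecular, x)
      if (is.null(cmp$final)) return(risk)
      cl <- cohort$clinical[match(ids, cohort$clinical$sample_id), , drop = FALSE]
      stats::predict(cmp$final, risk, cl)
    }
  }
  list(name = "cox_ridge", fit = fit)
}
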