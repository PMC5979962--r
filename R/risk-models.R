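#' Build the molecular feature matrix for a feature set
#'
#' Assembles a samples-by-features matrix from m2eQTL beta values and m2eGene
#' expression values. Either omics layer may be `NULL` (e.g. expression-only
#' cohorts use [substitute_cis_genes()] instead of raw probes).
#'
#' @param feature_set An `m2efm_feature_set`.
#' @param meth,expr [omics_matrix()] objects (or `NULL`).
#' @return A numeric matrix, samples in rows, features in columns.
#' @export
build_feature_matrix <- function(feature_set, meth = NULL, expr = NULL) {
  stopifnot(inherits(feature_set, "m2efm_feature_set"))
  blocks <- list()
  samples <- NULL
  if (!is.null(meth)) {
    probes <- intersect(feature_set$probes, meth$feature_ids)
    if (length(probes) < length(feature_set$probes))
      warning(length(feature_set$probes) - length(probes),
              " selected probe(s) absent from methylation matrix")
    blocks$meth <- t(meth$values[probes, , drop = FALSE])
    samples <- meth$sample_ids
  }
  if (!is.null(expr)) {
    genes <- intersect(feature_set$genes, expr$feature_ids)
    if (length(genes) < length(feature_set$genes))
      warning(length(feature_set$genes) - length(genes),
              " m2eGene(s) absent from expression matrix")
    blocks$expr <- t(expr$values[genes, , drop = FALSE])
    if (is.null(samples)) samples <- expr$sample_ids
    else {
      if (!identical(samples, expr$sample_ids))
        stop("meth and expr must share an identical sample order; see align_samples()")
    }
  }
  if (!length(blocks)) stop("at least one of meth or expr is required")
  do.call(cbind, unname(blocks))
}

#' Substitute cis genes for methylation probes (expression-only features)
#'
#' For cohorts without methylation data, each selected probe is replaced by
#' the expression of its proximal (cis) gene; a probe whose cis gene already
#' appears among the m2eGenes contributes no duplicate column, and probes
#' with no cis gene present in the expression matrix are dropped with a
#' warning.
#'
#' @param feature_set An `m2efm_feature_set`.
#' @param expr [omics_matrix()] of expression values.
#' @return A numeric matrix (samples x expression features).
#' @export
substitute_cis_genes <- function(feature_set, expr) {
  stopifnot(inherits(feature_set, "m2efm_feature_set"),
            inherits(expr, "omics_matrix"))
  cis_genes <- unname(feature_set$cis_map[feature_set$probes])
  cis_genes <- cis_genes[!is.na(cis_genes)]
  n_missing <- sum(!cis_genes %in% expr$feature_ids) +
    sum(!feature_set$probes %in% names(feature_set$cis_map))
  if (n_missing > 0)
    warning(n_missing, " probe(s) dropped: no cis gene available in expression data")
  cis_genes <- cis_genes[cis_genes %in% expr$feature_ids]
  genes <- intersect(feature_set$genes, expr$feature_ids)
  all_genes <- unique(c(cis_genes, genes))
  if (!length(all_genes)) stop("no expression features available for substitution")
  t(expr$values[all_genes, , drop = FALSE])
}

standardize_columns <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(x)[scale == 0], 5), collapse = ", "))
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

make_foldid <- function(n, nfolds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(nfolds), n))
}

#' Fit the penalized molecular model (ridge)
#'
#' Fits an L2-penalized (ridge) proportional-hazards or logistic regression
#' on the molecular features, the first stage of M2EFM. Features are
#' standardized internally (mean 0, sd 1) and the standardization parameters
#' are stored with the model, so held-out samples are scored with the
#' training means and standard deviations. The penalty weight is chosen by
#' k-fold cross-validation on the training samples only.
#'
#' @param features Numeric matrix, samples x features (named on both
#'   dimensions).
#' @param outcome A [survival_outcome()] (family `"proportional_hazards"`)
#'   or [binary_outcome()] (family `"logistic"`), covering all rows.
#' @param family `"proportional_hazards"` or `"logistic"`.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment (required).
#' @param rule `"min"` (penalty minimizing mean CV deviance, default) or
#'   `"1se"`.
#' @param lambda Optional fixed penalty weight; skips cross-validation.
#' @return An object of class `m2efm_molecular_model` with elements
#'   `family`, `feature_ids`, `coefficients` (on the standardized scale),
#'   `center`, `scale`, `lambda`, and `training_sample_ids`.
#' @export
fit_molecular_model <- function(features, outcome,
                                family = c("proportional_hazards", "logistic"),
                                nfolds = 10, seed = 1,
                                rule = c("min", "1se"), lambda = NULL) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  if (!is.matrix(features) || !is.numeric(features))
    stop("'features' must be a numeric matrix (samples x features)")
  if (any(!is.finite(features))) stop("non-finite feature values")
  ids <- rownames(features)
  if (is.null(ids)) stop("'features' must have sample ids as rownames")
  out <- subset_outcome(outcome, ids)
  y <- if (family == "proportional_hazards") {
    if (sum(out$event) < 2) stop("at least 2 events required")
    survival::Surv(out$time, out$event)
  } else {
    if (length(unique(out$label)) < 2) stop("both classes required")
    as.integer(out$label)
  }
  std <- standardize_columns(features)
  gfam <- if (family == "proportional_hazards") "cox" else "binomial"
  if (is.null(lambda)) {
    foldid <- make_foldid(nrow(features), nfolds, seed)
    cv <- glmnet::cv.glmnet(std$x, y, family = gfam, alpha = 0,
                            foldid = foldid, standardize = FALSE,
                            thresh = 1e-10)
    lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(std$x, y, family = gfam, alpha = 0,
                          standardize = FALSE, thresh = 1e-10)
  }
  beta <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = std$x,
                                 y = y, family = gfam, alpha = 0,
                                 standardize = FALSE, thresh = 1e-10))
  cn <- rownames(stats::coef(fit, s = lambda))
  if (gfam == "binomial") {
    intercept <- beta[cn == "(Intercept)"]
    beta <- beta[cn != "(Intercept)"]
  } else intercept <- 0
  structure(list(family = family, feature_ids = colnames(features),
                 coefficients = stats::setNames(beta, colnames(features)),
                 intercept = intercept,
                 center = std$center, scale = std$scale, lambda = lambda,
                 training_sample_ids = ids),
            class = "m2efm_molecular_model")
}

#' @export
print.m2efm_molecular_model <- function(x, ...) {
  cat(sprintf("m2efm_molecular_model [%s]: %d features, lambda = %.4g\n",
              x$family, length(x$feature_ids), x$lambda))
  invisible(x)
}

#' Compute molecular risk scores
#'
#' The molecular risk score is the exponential of the weighted sum of the
#' (training-standardized) model features: `exp(sum_j beta_j * x_js)`.
#' Higher scores indicate worse prognosis when hazard increases with the
#' linear predictor.
#'
#' @param model An `m2efm_molecular_model`.
#' @param features Numeric matrix (samples x features) containing every model
#'   feature.
#' @return Named numeric vector of positive risk scores.
#' @export
compute_risk_score <- function(model, features) {
  stopifnot(inherits(model, "m2efm_molecular_model"))
  missing <- setdiff(model$feature_ids, colnames(features))
  if (length(missing))
    stop("features missing from input: ",
         paste(utils::head(missing, 10), collapse = ", "))
  x <- features[, model$feature_ids, drop = FALSE]
  x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  lp <- drop(x %*% model$coefficients)
  stats::setNames(exp(lp), rownames(features))
}

#' Reduce AJCC stage labels
#'
#' Collapses AJCC stage strings (e.g. "Stage IIA", "iiib") to the four
#' principal stages I-IV, or to a stage-III indicator used when stage IV is
#' absent and stage I counts are small.
#'
#' @param label Character vector of stage labels.
#' @param mode `"four_level"` (default) or `"stage3_indicator"`.
#' @return Character vector in `{"I","II","III","IV"}`, or logical for
#'   `"stage3_indicator"`.
#' @export
collapse_stage <- function(label, mode = c("four_level", "stage3_indicator")) {
  mode <- match.arg(mode)
  core <- toupper(trimws(sub("(?i)^\\s*stage\\s*", "", label, perl = TRUE)))
  m <- regmatches(core, regexec("^(IV|III|II|I)[ABC]?$", core))
  base <- vapply(m, function(g) if (length(g)) g[2] else NA_character_,
                 character(1))
  if (anyNA(base))
    stop("unparseable stage label(s): ",
         paste(unique(label[is.na(base)]), collapse = ", "))
  if (mode == "four_level") base else base == "III"
}

#' Encode clinical covariates as a numeric design matrix
#'
#' Numeric covariates pass through; categorical covariates become indicator
#' contrasts with the most frequent level (in the data supplied, normally the
#' training split) as the reference. The factor level order is stored so test
#' samples are encoded identically.
#'
#' @param clinical A `clinical_table` (or data frame with `sample_id`).
#' @param covariates Character vector of column names to encode.
#' @param levels Optional list of factor level orders from a previous
#'   encoding (reference first); used to encode test data consistently.
#' @return A list with `x` (design matrix, samples x columns), `levels`, and
#'   `covariates`.
#' @export
encode_clinical <- function(clinical, covariates, levels = NULL) {
  stopifnot(all(covariates %in% colnames(clinical)))
  df <- clinical[, covariates, drop = FALSE]
  lev <- levels
  if (is.null(lev)) {
    lev <- list()
    for (col in covariates) {
      if (!is.numeric(df[[col]])) {
        tab <- sort(table(df[[col]]), decreasing = TRUE)
        lev[[col]] <- names(tab)  # most frequent first = reference
      }
    }
  }
  for (col in names(lev)) {
    vals <- as.character(df[[col]])
    extra <- setdiff(unique(vals), lev[[col]])
    df[[col]] <- factor(vals, levels = c(lev[[col]], extra))
  }
  mm <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  colnames(mm) <- make.names(colnames(mm), unique = TRUE)
  rownames(mm) <- clinical$sample_id
  list(x = mm, levels = lev, covariates = covariates)
}

#' Select clinical covariates by LASSO
#'
#' L1-penalized proportional-hazards or logistic regression over the encoded
#' candidate covariates; covariates with any nonzero indicator coefficient at
#' the cross-validated penalty are retained.
#'
#' @param clinical A `clinical_table`.
#' @param outcome A [survival_outcome()] or [binary_outcome()].
#' @param candidates Covariate column names to consider.
#' @param family `"proportional_hazards"` or `"logistic"`.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment (required).
#' @return Character vector of selected covariate names (possibly empty,
#'   with a warning).
#' @export
select_clinical_covariates <- function(clinical, outcome, candidates,
                                       family = c("proportional_hazards", "logistic"),
                                       nfolds = 10, seed = 1) {
  family <- match.arg(family)
  # zero-variance candidates can never be selected and break standardization
  usable <- candidates[vapply(candidates, function(col)
    length(unique(clinical[[col]])) > 1, logical(1))]
  if (!length(usable)) {
    warning("no clinical covariate with variation; empty selection")
    return(character(0))
  }
  enc <- encode_clinical(clinical, usable)
  out <- subset_outcome(outcome, clinical$sample_id)
  y <- if (family == "proportional_hazards")
    survival::Surv(out$time, out$event)
  else as.integer(out$label)
  gfam <- if (family == "proportional_hazards") "cox" else "binomial"
  x <- enc$x
  if (ncol(x) < 2)  # glmnet needs >= 2 columns; pad with an inert null column
    x <- cbind(x, ..pad = 0)
  foldid <- make_foldid(nrow(x), nfolds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = gfam, alpha = 1, foldid = foldid)
  beta <- stats::coef(cv, s = "lambda.min")
  beta <- beta[setdiff(rownames(beta), "(Intercept)"), , drop = FALSE]
  nz_cols <- rownames(beta)[as.numeric(beta) != 0]
  sel <- usable[vapply(usable, function(col)
    any(startsWith(nz_cols, col)), logical(1))]
  if (!length(sel))
    warning("LASSO selected no clinical covariates; final model will use the molecular term only")
  sel
}

#' Fit the final (unpenalized) model
#'
#' Second M2EFM stage: an ordinary proportional-hazards (Breslow ties) or
#' logistic regression of the outcome on the log molecular risk score (the
#' penalized linear predictor) together with the selected clinical
#' covariates. The final risk score remains the exponential of a weighted
#' sum of features.
#'
#' @param risk Named vector of molecular risk scores (from
#'   [compute_risk_score()]).
#' @param clinical A `clinical_table` covering the scored samples (or `NULL`
#'   for a molecular-only model).
#' @param outcome A [survival_outcome()] or [binary_outcome()].
#' @param family `"proportional_hazards"` or `"logistic"`.
#' @param covariates Clinical covariate names to include (e.g. from
#'   [select_clinical_covariates()]).
#' @return An object of class `m2efm_final_model` with the fitted model, a
#'   coefficient table with hazard/odds ratios and Wald 95% CIs, and the
#'   clinical encoding.
#' @export
fit_final_model <- function(risk, clinical = NULL, outcome,
                            family = c("proportional_hazards", "logistic"),
                            covariates = character(0)) {
  family <- match.arg(family)
  ids <- names(risk)
  if (is.null(ids)) stop("'risk' must be a named vector of sample scores")
  if (any(risk <= 0)) stop("risk scores must be positive (exp of a linear predictor)")
  out <- subset_outcome(outcome, ids)
  df <- data.frame(molecular_risk = log(risk), row.names = ids)
  enc <- NULL
  if (length(covariates)) {
    if (is.null(clinical)) stop("covariates requested but no clinical table given")
    cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
    if (anyNA(cl$sample_id)) stop("clinical table missing scored samples")
    enc <- encode_clinical(cl, covariates)
    df <- cbind(df, as.data.frame(enc$x))
  }
  if (family == "proportional_hazards") {
    .y <- survival::Surv(out$time, out$event)
    fit <- survival::coxph(.y ~ ., data = df, ties = "breslow")
  } else {
    df$.y <- as.integer(out$label)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  }
  coefs <- stats::coef(fit)
  coefs <- coefs[setdiff(names(coefs), "(Intercept)")]
  if (anyNA(coefs))
    stop("collinear or inestimable term(s): ",
         paste(names(coefs)[is.na(coefs)], collapse = ", "))
  se <- sqrt(diag(stats::vcov(fit)))[names(coefs)]
  table <- data.frame(
    term = names(coefs), coef = unname(coefs),
    ratio = exp(unname(coefs)),
    lower95 = exp(unname(coefs) - 1.96 * se),
    upper95 = exp(unname(coefs) + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(unname(coefs) / se)),
    row.names = NULL)
  structure(list(family = family, fit = fit, terms = table,
                 covariates = covariates, encoding = enc),
            class = "m2efm_final_model")
}

#' @export
print.m2efm_final_model <- function(x, ...) {
  cat(sprintf("m2efm_final_model [%s]\n", x$family))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Predict final risk scores
#'
#' @param object An `m2efm_final_model`.
#' @param risk Named vector of molecular risk scores for the new samples.
#' @param clinical Clinical table for the new samples (if the model has
#'   clinical terms).
#' @param ... Unused.
#' @return Named numeric vector: `exp(linear predictor)` of the final model.
#' @export
predict.m2efm_final_model <- function(object, risk, clinical = NULL, ...) {
  ids <- names(risk)
  df <- data.frame(molecular_risk = log(risk), row.names = ids)
  if (length(object$covariates)) {
    cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
    enc <- encode_clinical(cl, object$covariates, levels = object$encoding$levels)
    df <- cbind(df, as.data.frame(enc$x))
  }
  cf <- stats::coef(object$fit)
  terms <- setdiff(names(cf), "(Intercept)")
  lp <- drop(as.matrix(df[, terms, drop = FALSE]) %*% cf[terms])
  if ("(Intercept)" %in% names(cf)) lp <- lp + cf[["(Intercept)"]]
  stats::setNames(exp(unname(lp)), ids)
}

#' Fit a comparator ridge model without feature pre-selection
#'
#' Reference model: ridge regression over all genes plus the most variable
#' methylation probes (ranked by median absolute deviation and truncated to
#' `mad_filter` probes, by default the number of genes), followed by the same
#' unpenalized clinical integration as M2EFM's final stage.
#'
#' @param meth [omics_matrix()] of betas, or `NULL` for expression-only.
#' @param expr [omics_matrix()] of expression values.
#' @param clinical,outcome,family,covariates As in [fit_final_model()].
#' @param mad_filter Number of most-variable probes to keep (default:
#'   number of genes).
#' @param nfolds,seed Cross-validation controls, as in
#'   [fit_molecular_model()].
#' @return List with `molecular` (the ridge `m2efm_molecular_model`) and
#'   `final` (the clinical-integrated `m2efm_final_model`, or `NULL` when no
#'   covariates are supplied).
#' @export
fit_comparator_ridge <- function(meth = NULL, expr, clinical = NULL, outcome,
                                 family = c("proportional_hazards", "logistic"),
                                 covariates = character(0),
                                 mad_filter = NULL, nfolds = 10, seed = 1) {
  family <- match.arg(family)
  blocks <- list(t(expr$values))
  if (!is.null(meth)) {
    if (is.null(mad_filter)) mad_filter <- length(expr$feature_ids)
    probes <- mad_top_features(meth, mad_filter)
    blocks <- c(list(t(meth$values[probes, , drop = FALSE])), blocks)
  }
  x <- do.call(cbind, blocks)
  mol <- fit_molecular_model(x, outcome, family, nfolds = nfolds, seed = seed)
  final <- NULL
  if (length(covariates)) {
    risk <- compute_risk_score(mol, x)
    final <- fit_final_model(risk, clinical, outcome, family, covariates)
  }
  list(molecular = mol, final = final)
}

#' Rank features by median absolute deviation
#'
#' @param x An [omics_matrix()].
#' @param n Number of most-variable features to return.
#' @return Character vector of feature ids, most variable first.
#' @export
mad_top_features <- function(x, n) {
  stopifnot(inherits(x, "omics_matrix"))
  mads <- apply(x$values, 1, stats::mad)
  ord <- order(-mads, x$feature_ids)
  x$feature_ids[ord][seq_len(min(n, length(mads)))]
}
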