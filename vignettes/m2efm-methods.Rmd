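---
title: "Methylation-to-expression feature models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-to-expression feature models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m2efm)
```

## The modeling problem

Tumors accumulate DNA-methylation changes at CpG loci that disrupt the
regulation of nearby (and occasionally distant) genes. A locus whose
methylation level associates with expression differences in tumor tissue is
here called an **m2eQTL** (methylation-to-expression QTL), and the genes it
regulates **m2eGenes**. The premise of a methylation-to-expression feature
model (M2EFM) is that this regulatory disruption carries prognostic
information beyond standard clinical covariates, and that a model built on a
small m2eQTL/m2eGene signature transfers across cohorts better than a
transcriptome-wide fit.

The package implements the full pipeline: candidate differentially
methylated probes (normally supplied from an external tumor/normal study)
are screened against expression in matched tumor samples; the strongest
associations define the molecular feature set; a two-stage risk model is
fit; and models are compared with a repeated-split evaluation harness.

## The two-stage risk model

**Stage 1 (penalized molecular model).** Let \(x_s\) be the vector of
molecular features for sample \(s\) — m2eQTL beta values and/or m2eGene
expression, standardized to mean 0 and unit variance on the training
samples. A Cox proportional-hazards (or logistic, for binary endpoints)
regression with an L2 (ridge) penalty is fit by `fit_molecular_model()`,
minimizing the negative log partial likelihood plus
\(\lambda \lVert\beta\rVert_2^2/2\), with \(\lambda\) chosen by k-fold
cross-validation on the training samples only. Ridge is used deliberately:
the features are selected beforehand and strongly correlated (a probe and
the gene it regulates), so shrinkage without sparsity is appropriate. The
**molecular risk score** is
\(r_s = \exp(\beta^\top x_s)\), the exponential of the weighted sum of the
model features (`compute_risk_score()`).

**Stage 2 (unpenalized final model).** `fit_final_model()` regresses the
outcome on \(\log r_s\) (the penalized linear predictor) together with a
small set of clinical covariates, without penalty, reporting hazard or odds
ratios with Wald 95% intervals. Entering the molecular term on the log
scale keeps the final score itself a weighted sum of features, so its
exponential remains interpretable as a relative hazard; whether the
original formulation entered \(r_s\) or \(\log r_s\) is not documented, and
the log scale was chosen here as the package's own design decision because
it keeps the final model linear and the molecular hazard ratio
interpretable per log-unit of risk.

Clinical covariates are chosen by LASSO (`select_clinical_covariates()`):
candidates are encoded as indicator contrasts (reference level = most
frequent in the training data, for determinism), an L1-penalized fit is
cross-validated, and covariates with any nonzero coefficient at the
deviance-minimizing penalty are retained. AJCC stage strings are collapsed
to the principal stages I–IV (`collapse_stage()`), or to a stage-III
indicator for cohorts lacking stage IV cases.

**Expression-only transfer.** Validation cohorts usually lack methylation
arrays. `substitute_cis_genes()` replaces each selected probe with the
expression of its proximal (cis) gene, deduplicating against genes already
in the signature, so the trained feature *definition* transfers to any
expression cohort. When the cis genes mediate the methylation effect —
which the synthetic generator makes exactly true — the expression-only
model loses little discriminative power.

## m2eQTL discovery

`associate()` fits, for every candidate probe–gene pair, a simple linear
regression of expression on beta value and reports the OLS slope with its
two-sided t-test p-value. Betas are used untransformed (no M-values): they
are the stored unit, bounded in [0, 1], and the association slope then has
the direct reading "expression change per unit methylation". Pairs on the
same chromosome within the **cis window** (default 1 Mb, closed boundary —
the conventional eQTL choice) are always tested; `include_trans = TRUE`
extends the scan genome-wide. Benjamini–Hochberg false-discovery rates are
computed *within* the cis and trans classes, whose test counts differ by
orders of magnitude. `discover_feature_set()` keeps pairs at
`q <= q_threshold` (default 0.05), ranks them by absolute slope ("largest
effects"; p-value ranking is available), truncates to configurable probe
and gene budgets, and resolves each probe's cis gene. Ties break by probe
then gene id, so the output is invariant to input order. The published
signature size (115 m2eGenes) is a *result* of thresholds on a specific
cohort, not a parameter of the method.

## Evaluation harness

`run_split_harness()` reproduces the repeated-split design: each repeat
draws a 70/30 train/test partition (training size `floor(0.7 n)`), fits
every model specification on the identical training set — feature
discovery and clinical selection re-run *inside* the training set, so no
information leaks across the split — and records the held-out C-index (or
ROC AUC for binary endpoints). Splits are stratified by the event
indicator by default; the source experiment does not say whether its
splits were stratified, and stratification was adopted here to prevent
degenerate event-free test halves at small n. Paired model comparisons use
a two-tailed Wilcoxon signed-rank test (`compare_models()`), exact for 25
or fewer untied pairs and a continuity-corrected normal approximation
above, with failed splits excluded pairwise.

Supporting metrics, each validated against independent oracles in the test
suite:

* `concordance_index()` — Harrell's C over pairs whose earlier time is an
  observed event; risk ties count 1/2; tied times are incomparable.
* `auc_binary()` — Mann–Whitney AUC from midranks.
* `integrated_brier_score()` — IPCW Brier score (censoring distribution by
  Kaplan–Meier on the censoring indicator, with the left-limit
  \(\hat G(T_i^-)\) weighting events), averaged over a time grid by
  trapezoidal integration.
* `assign_risk_groups()` — low/medium/high by the training 25th/75th
  percentiles (type-7 linear interpolation, the most common convention;
  configurable), boundaries closed into medium; `group_hazard_ratios()`
  fits the group indicators unpenalized against the low-risk reference.
* `npv_ppv_at_horizon()` — the risk cutoff equalizing time-dependent
  sensitivity and specificity under the cumulative-case/dynamic-control
  ROC with IPCW on the training set, applied to the test set; both the
  IPCW predictive values and raw classification counts (over samples with
  known status at the horizon) are returned, since it is ambiguous which
  of the two a given report used.
* `variance_inflation_factor()` — \(1/(1-R^2)\) of the molecular score
  regressed on covariates, to show the score carries information
  independent of, e.g., receptor status and subtype.
* `infer_receptor_status()` — a two-component Gaussian mixture (EM, via
  mclust) on the first principal component of receptor-marker expression,
  oriented so the high-expression component is "positive"; used to impute
  missing receptor annotations.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the method assumes,
with a full ground-truth manifest. Null probes draw betas from Beta(2, 2);
planted probes are bimodal across samples (Beta(8, 2) / Beta(2, 8) halves),
mimicking a differentially methylated locus. A planted gene's expression is
`5 + meth_effect * beta + N(0, noise_sd)`; null genes are pure noise.
Survival is exponential (Weibull shape exposed for robustness checks) with
hazard proportional to `exp(lp)`, where `lp` sums `log_hazard_per_sd` per
standardized unit of each prognostic gene (the planted m2eGenes first, so
cis genes fully mediate the methylation effect) plus centered-age and
stage-III terms. Censoring is independent exponential with its rate solved
numerically so the expected censored fraction matches `censoring_rate`. A
binary response follows `Bernoulli(plogis(intercept + slope * lp))`.
Annotation places each planted probe 5 kb from its gene (safely cis at the
1 Mb window, with genes 3 Mb apart so each probe is cis to exactly one
gene) and null probes on a gene-free chromosome. Demographics (age
N(58, 12) truncated to [25, 90]; stage frequencies skewed toward stage II)
are cosmetic but roughly match breast-cancer cohorts.

Defaults — 300 samples, 500 probes and genes, 20 planted pairs with slope
1.5 over noise sd 0.5, 10 prognostic genes at log-HR 0.5 per sd, 30%
censoring — are the benchmark conditions used throughout the tests;
`default_benchmark_suite()` freezes null/weak/strong and small/large
variants under fixed, distinct seeds. The strong benchmark uses n = 400;
the test suite evaluates it over 10 repeated splits, a problem size chosen
so the whole suite runs in well under a minute per end-to-end check.

**What the generator does not emulate:** array noise structure, probe
cross-hybridization, batch effects, non-proportional hazards, correlated
gene modules, or the tumor/normal differential-methylation screen itself
(candidate probes are taken as given, as in the real pipeline, where the
probe list comes from an external field-effect study). Tests passing on
these cohorts therefore demonstrate correctness of the machinery and
recoverability of planted effects under the stated noise model — not
clinical performance on real arrays.

## Numerical choices and degenerate inputs

* Penalized fits use glmnet with features standardized *before* the call
  (parameters stored with the model); held-out samples are always scored
  with training means and standard deviations, never re-standardized.
* Cross-validation: 10 folds, fold assignment from a mandatory seed,
  penalty at minimum mean CV deviance (`rule = "min"`; `"1se"` available).
* Cox ties use the Breslow approximation throughout.
* Zero-variance probes/genes are skipped with a logged count during
  association; zero-variance covariates are excluded before LASSO (a
  single remaining candidate is padded with an inert null column, since
  the coordinate-descent solver requires at least two).
* Exact collinearity in the final model is a hard error naming the term.
* An exact-fit regression in `variance_inflation_factor()` returns
  infinity rather than an error.
* The Fisher-exact odds ratio is reported as the conditional MLE (the
  convention of standard exact-test implementations, and the one matching
  published values); the cross-product ratio is also emitted.
* The comparator ridge model filters probes by median absolute deviation
  to roughly the number of genes before fitting, mirroring the reference
  "no pre-selection" design.

## Known limitations

* The harness re-runs discovery per split but shares one candidate probe
  list across splits; a fully nested probe screen would require matched
  normal tissue, which is out of scope.
* The IPCW estimators assume censoring independent of covariates; with
  covariate-dependent censoring the Brier score and predictive values are
  biased.
* `infer_receptor_status()` assumes an approximately bimodal marker
  distribution; it warns (rather than fails) when the fitted components
  are separated by less than two pooled standard deviations.
* Expression-only transfer assumes the cis gene mediates the probe's
  effect; probes acting in trans lose their signal under substitution.
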