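#' Classify a probe-gene pair as cis or trans
#'
#' A pair is cis when probe and gene are annotated on the same chromosome and
#' their positions differ by at most `cis_window` base pairs (closed
#' boundary); otherwise trans. Unannotated features classify as trans with a
#' warning.
#'
#' @param probe_id,gene_id Feature ids to look up in `annotation`.
#' @param annotation Annotation data frame from [read_annotation()] covering
#'   probes and genes.
#' @param cis_window Window in bp (default 1 Mb).
#' @return A list with `relation` ("cis"/"trans") and `distance` (bp, or `NA`
#'   for cross-chromosome or unannotated pairs).
#' @export
classify_cis_trans <- function(probe_id, gene_id, annotation, cis_window = 1e6) {
  pi <- match(probe_id, annotation$feature_id)
  gi <- match(gene_id, annotation$feature_id)
  if (is.na(pi) || is.na(gi)) {
    warning("unannotated feature in pair (", probe_id, ", ", gene_id,
            "); classified trans")
    return(list(relation = "trans", distance = NA_real_))
  }
  if (annotation$chrom[pi] != annotation$chrom[gi])
    return(list(relation = "trans", distance = NA_real_))
  d <- abs(annotation$position[pi] - annotation$position[gi])
  list(relation = if (d <= cis_window) "cis" else "trans", distance = d)
}

#' Associate methylation with expression (m2eQTL scan)
#'
#' For each candidate probe-gene pair, fits a simple linear regression of the
#' gene's expression on the probe's beta value and reports the ordinary
#' least-squares slope with its two-sided p-value. Cis pairs (same chromosome,
#' within `cis_window`) are always tested; setting `include_trans = TRUE`
#' additionally tests all remaining pairs genome-wide. False discovery rates
#' (Benjamini-Hochberg) are computed separately within the cis and trans
#' classes, whose test counts differ by orders of magnitude.
#'
#' @param meth [omics_matrix()] of beta values restricted to candidate probes.
#' @param expr [omics_matrix()] of expression values.
#' @param annotation Annotation covering probes and genes (see
#'   [read_annotation()]).
#' @param cis_window Cis window in bp, closed boundary (default 1 Mb).
#' @param include_trans Test non-cis pairs genome-wide? Default `FALSE`.
#' @return A data frame with columns `probe_id`, `gene_id`, `slope`,
#'   `p_value`, `q_value`, `relation`, `distance`.
#' @export
associate <- function(meth, expr, annotation, cis_window = 1e6,
                      include_trans = FALSE) {
  stopifnot(inherits(meth, "omics_matrix"), inherits(expr, "omics_matrix"))
  shared <- intersect(meth$sample_ids, expr$sample_ids)
  if (length(shared) < 10)
    stop("associate requires at least 10 shared samples (found ",
         length(shared), ")")
  M <- meth$values[, shared, drop = FALSE]
  E <- expr$values[, shared, drop = FALSE]
  n <- length(shared)

  sd_p <- apply(M, 1, stats::sd)
  sd_g <- apply(E, 1, stats::sd)
  drop_p <- rownames(M)[sd_p == 0]
  drop_g <- rownames(E)[sd_g == 0]
  if (length(drop_p))
    message(sprintf("associate: skipping %d zero-variance probe(s): %s",
                    length(drop_p), paste(utils::head(drop_p, 5), collapse = ", ")))
  if (length(drop_g))
    message(sprintf("associate: skipping %d zero-variance gene(s): %s",
                    length(drop_g), paste(utils::head(drop_g, 5), collapse = ", ")))
  M <- M[sd_p > 0, , drop = FALSE]
  E <- E[sd_g > 0, , drop = FALSE]
  sd_p <- sd_p[sd_p > 0]; sd_g <- sd_g[sd_g > 0]
  if (!nrow(M) || !nrow(E)) stop("no testable probes or genes left")

  # all pairwise correlations at once; slope and t-test follow analytically
  r <- stats::cor(t(M), t(E))
  slope <- r * outer(1 / sd_p, sd_g)
  r2 <- pmin(r^2, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)

  ann_p <- annotation[match(rownames(M), annotation$feature_id), ]
  ann_g <- annotation[match(rownames(E), annotation$feature_id), ]
  same_chr <- outer(ann_p$chrom, ann_g$chrom, `==`)
  same_chr[is.na(same_chr)] <- FALSE
  dist <- abs(outer(ann_p$position, ann_g$position, `-`))
  is_cis <- same_chr & dist <= cis_window

  keep <- if (include_trans) is_cis | TRUE else is_cis
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) stop("no probe-gene pairs to test within the cis window")
  res <- data.frame(
    probe_id = rownames(M)[idx[, 1]],
    gene_id = rownames(E)[idx[, 2]],
    slope = slope[idx],
    p_value = pval[idx],
    relation = ifelse(is_cis[idx], "cis", "trans"),
    distance = ifelse(same_chr[idx], dist[idx], NA_real_),
    stringsAsFactors = FALSE)
  res$q_value <- NA_real_
  for (rel in unique(res$relation)) {
    sel <- res$relation == rel
    res$q_value[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
  }
  res <- res[order(res$probe_id, res$gene_id), ]
  rownames(res) <- NULL
  res[, c("probe_id", "gene_id", "slope", "p_value", "q_value",
          "relation", "distance")]
}

#' Select the m2eQTL / m2eGene feature set
#'
#' Filters association records at a q-value threshold, ranks the survivors by
#' effect size (absolute slope, or p-value), and truncates to at most
#' `max_probes` distinct probes and `max_genes` distinct genes. Each selected
#' probe is assigned its nearest annotated gene as its cis gene, enabling the
#' expression-only substitution of [substitute_cis_genes()]. Ties are broken
#' by probe id then gene id, so the result does not depend on input order.
#'
#' @param records Association data frame from [associate()].
#' @param annotation Annotation data frame; used for the cis-gene map.
#' @param q_threshold FDR threshold (default 0.05).
#' @param max_probes,max_genes Truncation limits (default `Inf`).
#' @param ranking `"abs_slope"` (largest effects, default) or `"p_value"`.
#' @param cis_window Window used when the cis gene must be found by position.
#' @return An object of class `m2efm_feature_set`: list with `probes`,
#'   `genes`, `cis_map` (named character vector probe -> gene) and `records`
#'   (the retained associations).
#' @export
discover_feature_set <- function(records, annotation, q_threshold = 0.05,
                                 max_probes = Inf, max_genes = Inf,
                                 ranking = c("abs_slope", "p_value"),
                                 cis_window = 1e6) {
  ranking <- match.arg(ranking)
  stopifnot(nrow(records) > 0)
  keep <- records[records$q_value <= q_threshold, , drop = FALSE]
  if (!nrow(keep))
    stop("no associations pass q <= ", q_threshold,
         "; consider raising the threshold")
  ord <- if (ranking == "abs_slope")
    order(-abs(keep$slope), keep$probe_id, keep$gene_id)
  else
    order(keep$p_value, keep$probe_id, keep$gene_id)
  keep <- keep[ord, , drop = FALSE]
  probes <- unique(keep$probe_id)
  genes <- unique(keep$gene_id)
  if (is.finite(max_probes)) probes <- utils::head(probes, max_probes)
  if (is.finite(max_genes)) genes <- utils::head(genes, max_genes)
  keep <- keep[keep$probe_id %in% probes & keep$gene_id %in% genes, ,
               drop = FALSE]
  cis_map <- vapply(probes, nearest_gene_for_probe, character(1),
                    annotation = annotation, cis_window = cis_window,
                    gene_ids = unique(records$gene_id))
  cis_map <- cis_map[nzchar(cis_map)]
  structure(list(probes = probes, genes = genes, cis_map = cis_map,
                 records = keep),
            class = "m2efm_feature_set")
}

nearest_gene_for_probe <- function(probe_id, annotation, cis_window = 1e6,
                                   gene_ids = character(0)) {
  i <- match(probe_id, annotation$feature_id)
  if (is.na(i)) return("")
  if (nzchar(annotation$nearest_gene[i])) return(annotation$nearest_gene[i])
  # fall back to the closest annotated gene on the same chromosome
  cand <- annotation[annotation$feature_id %in% gene_ids &
                       annotation$chrom == annotation$chrom[i], , drop = FALSE]
  if (!nrow(cand)) return("")
  d <- abs(cand$position - annotation$position[i])
  ok <- d <= cis_window
  if (!any(ok)) return("")
  cand$feature_id[ok][which.min(d[ok])]
}

#' @export
print.m2efm_feature_set <- function(x, ...) {
  cat(sprintf("m2efm_feature_set: %d m2eQTL probes, %d m2eGenes, %d cis-mapped\n",
              length(x$probes), length(x$genes), length(x$cis_map)))
  invisible(x)
}

#' Screen candidate probes by differential methylation
#'
#' Optional helper for synthetic runs: two-sample Welch t-test of each probe's
#' beta values between two sample groups (e.g. tumor vs normal), returning
#' probes with BH-adjusted p below a threshold. Real analyses normally supply
#' an externally derived differentially-methylated probe list instead.
#'
#' @param meth [omics_matrix()] of betas.
#' @param group Logical vector along samples (TRUE = case).
#' @param q_threshold FDR threshold (default 0.05).
#' @return Character vector of probe ids.
#' @export
screen_probes <- function(meth, group, q_threshold = 0.05) {
  stopifnot(inherits(meth, "omics_matrix"),
            length(group) == length(meth$sample_ids))
  p <- apply(meth$values, 1, function(v) {
    if (stats::sd(v[group]) == 0 && stats::sd(v[!group]) == 0) return(NA_real_)
    stats::t.test(v[group], v[!group])$p.value
  })
  q <- stats::p.adjust(p, method = "BH")
  meth$feature_ids[!is.na(q) & q <= q_threshold]
}

#' Serialize / deserialize a feature set as JSON
#'
#' @param x An `m2efm_feature_set`.
#' @param path Output (or input) JSON path.
#' @return `write_feature_set` returns `path` invisibly; `read_feature_set`
#'   returns the feature set.
#' @export
write_feature_set <- function(x, path) {
  stopifnot(inherits(x, "m2efm_feature_set"))
  jsonlite::write_json(
    list(probes = x$probes, genes = x$genes,
         cis_map = as.list(x$cis_map), schema_version = 1L),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(probes = as.character(obj$probes),
                 genes = as.character(obj$genes),
                 cis_map = unlist(obj$cis_map),
                 records = NULL),
            class = "m2efm_feature_set")
}
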