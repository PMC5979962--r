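#' Build a 2x2 contingency table over a gene background
#'
#' Cross-classifies the genes of a stated background universe by membership
#' in the signature and in the target set. Signature or target genes outside
#' the background are dropped with a warning; cells are computed from set
#' intersections against the background only, so
#' `a + b + c + d = |background|`.
#'
#' @param signature Character vector of signature genes (e.g. the m2eGenes).
#' @param target Character vector, the gene set tested for enrichment.
#' @param background Character vector, the gene universe (e.g. all genes in
#'   the expression profiles). Must be passed explicitly.
#' @return Integer vector `c(a, b, c, d)`: signature-and-target,
#'   signature-only, target-only, neither.
#' @export
build_contingency <- function(signature, target, background) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be non-empty")
  signature <- unique(as.character(signature))
  target <- unique(as.character(target))
  out_sig <- setdiff(signature, background)
  if (length(out_sig))
    warning(length(out_sig), " signature gene(s) outside the background dropped")
  out_tgt <- setdiff(target, background)
  if (length(out_tgt))
    warning(length(out_tgt), " target gene(s) outside the background dropped")
  sig <- intersect(signature, background)
  tgt <- intersect(target, background)
  if (!length(sig)) stop("signature has no genes in the background")
  a <- length(intersect(sig, tgt))
  b <- length(sig) - a
  cc <- length(tgt) - a
  d <- length(background) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration (summing the
#' probabilities of tables no more likely than the observed one) and the
#' odds ratio as the conditional maximum-likelihood estimate of the
#' noncentral hypergeometric parameter. The simple cross-product estimate
#' `ad / bc` is also reported.
#'
#' @param table Integer vector `c(a, b, c, d)` (see [build_contingency()])
#'   or a 2x2 matrix.
#' @return An `enrichment_result`: list with `table`, `odds_ratio`
#'   (conditional MLE), `cross_product_or` and `p_value`.
#' @export
fisher_exact <- function(table) {
  if (is.matrix(table)) table <- as.vector(t(table))
  stopifnot(length(table) == 4, all(table >= 0))
  m <- matrix(table, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: odds ratio undefined")
  ft <- stats::fisher.test(m)
  cp <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  structure(list(table = stats::setNames(as.integer(table), c("a", "b", "c", "d")),
                 odds_ratio = unname(ft$estimate),
                 cross_product_or = cp,
                 p_value = ft$p.value),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: a=%d b=%d c=%d d=%d  OR=%.3f (cross-product %.3f)  p=%.3g\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"],
              x$odds_ratio, x$cross_product_or, x$p_value))
  invisible(x)
}

#' Enrichment of a signature against a collection of gene sets
#'
#' Runs [build_contingency()] + [fisher_exact()] for each set and adjusts
#' p-values by Benjamini-Hochberg.
#'
#' @param signature Character vector of signature genes.
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param background Character vector, the gene universe.
#' @return Data frame: `set`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `cross_product_or`, `p_value`, `q_value`.
#' @export
enrich_gene_sets <- function(signature, sets, background) {
  stopifnot(length(sets) >= 1)
  rows <- lapply(names(sets), function(nm) {
    tab <- suppressWarnings(build_contingency(signature, sets[[nm]], background))
    res <- fisher_exact(tab)
    data.frame(set = nm, a = tab[["a"]], b = tab[["b"]], c = tab[["c"]],
               d = tab[["d"]], odds_ratio = res$odds_ratio,
               cross_product_or = res$cross_product_or,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}
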