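#' Construct an omics matrix
#'
#' An `omics_matrix` is a features-by-samples numeric matrix carrying either
#' DNA-methylation beta values (fractions in \[0, 1\]) or expression values
#' (finite reals), with unique feature and sample identifiers.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param kind Either `"methylation_beta"` or `"expression"`.
#' @return An object of class `omics_matrix`: a list with elements
#'   `feature_ids`, `sample_ids`, `values` and `kind`.
#' @export
omics_matrix <- function(values, kind = c("methylation_beta", "expression")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  feature_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("'values' must have rownames (features) and colnames (samples)")
  x <- structure(
    list(feature_ids = feature_ids, sample_ids = sample_ids,
         values = values, kind = kind),
    class = "omics_matrix")
  validate_omics_matrix(x)
  x
}

validate_omics_matrix <- function(x) {
  dup_f <- unique(x$feature_ids[duplicated(x$feature_ids)])
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(utils::head(dup_f, 5), collapse = ", "))
  dup_s <- unique(x$sample_ids[duplicated(x$sample_ids)])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(utils::head(dup_s, 5), collapse = ", "))
  if (!identical(dim(x$values), c(length(x$feature_ids), length(x$sample_ids))))
    stop("matrix dimensions do not match id lengths")
  if (x$kind == "methylation_beta") {
    v <- x$values
    bad <- which(!is.na(v) & (v < 0 | v > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("beta value outside [0, 1] at feature '%s', sample '%s'",
                   x$feature_ids[bad[1, 1]], x$sample_ids[bad[1, 2]]))
  } else {
    if (any(is.infinite(x$values)))
      stop("expression values must be finite")
  }
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              x$kind, length(x$feature_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Subset an omics matrix by feature and/or sample ids
#'
#' @param x An `omics_matrix`.
#' @param features,samples Character vectors of ids to keep (in the given
#'   order); `NULL` keeps all.
#' @return An `omics_matrix` restricted to the requested ids.
#' @export
subset_omics <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  f <- if (is.null(features)) x$feature_ids else features
  s <- if (is.null(samples)) x$sample_ids else samples
  missing_f <- setdiff(f, x$feature_ids)
  if (length(missing_f))
    stop("features not present: ", paste(utils::head(missing_f, 5), collapse = ", "))
  missing_s <- setdiff(s, x$sample_ids)
  if (length(missing_s))
    stop("samples not present: ", paste(utils::head(missing_s, 5), collapse = ", "))
  omics_matrix(x$values[f, s, drop = FALSE], x$kind)
}

#' Read a features-by-samples matrix from TSV
#'
#' Expects a header row of sample ids and feature ids in the first column.
#' Features containing any missing value are dropped (with a message); no
#' imputation is performed. Gzip-compressed files are read transparently.
#'
#' @param path Path to a TSV (optionally .gz) file.
#' @param kind Either `"methylation_beta"` or `"expression"`.
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, kind = c("methylation_beta", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no features in ", path)
  sample_ids <- colnames(df)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample column: ", paste(dup_s, collapse = ", "))
  feature_ids <- df[[1]]
  dup_f <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup_f))
    stop("duplicate feature id: ", paste(utils::head(dup_f, 5), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(vals) & !is.na(raw) & nzchar(trimws(raw)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                 raw[bad[1, 1], bad[1, 2]], feature_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  dimnames(vals) <- list(feature_ids, sample_ids)
  n_missing <- sum(!stats::complete.cases(vals))
  if (n_missing > 0) {
    message(sprintf("read_matrix: dropping %d feature(s) with missing values", n_missing))
    vals <- vals[stats::complete.cases(vals), , drop = FALSE]
    if (nrow(vals) == 0L) stop("no features left after dropping missing values")
  }
  omics_matrix(vals, kind)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix()]: writes a header row of sample ids and feature
#' ids in a leading `feature_id` column.
#'
#' @param x An `omics_matrix`.
#' @param path Output path (".gz" suffix writes gzip).
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = x$feature_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", x$sample_ids)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
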