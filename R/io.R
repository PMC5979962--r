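#' Construct a survival outcome
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param time Positive follow-up times (one unit throughout a cohort).
#' @param event Logical (or 0/1): `TRUE` = event observed, `FALSE` =
#'   right-censored.
#' @return A `survival_outcome` object.
#' @export
survival_outcome <- function(sample_ids, time, event) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in outcome")
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    stop("sample_ids, time and event must have equal length")
  if (any(is.na(time)) || any(time <= 0)) stop("survival time must be > 0")
  if (any(is.na(event))) stop("event indicator must be 0/1 or logical")
  structure(list(sample_ids = sample_ids, time = time, event = event),
            class = "survival_outcome")
}

#' Construct a binary outcome
#'
#' @param sample_ids Character vector of unique sample ids.
#' @param label Logical (or 0/1) per-sample label (e.g. pathologic complete
#'   response).
#' @return A `binary_outcome` object.
#' @export
binary_outcome <- function(sample_ids, label) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in outcome")
  label <- as.logical(label)
  if (length(label) != length(sample_ids)) stop("one label per sample required")
  if (any(is.na(label))) stop("label must be 0/1 or logical")
  structure(list(sample_ids = sample_ids, label = label),
            class = "binary_outcome")
}

subset_outcome <- function(outcome, ids) {
  idx <- match(ids, outcome$sample_ids)
  if (any(is.na(idx))) stop("outcome missing samples: ",
                            paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  if (inherits(outcome, "survival_outcome"))
    survival_outcome(ids, outcome$time[idx], outcome$event[idx])
  else
    binary_outcome(ids, outcome$label[idx])
}

#' Read an outcome table from TSV
#'
#' Survival mode expects columns `sample_id`, `time`, `event` (event coercible
#' to 0/1); binary mode expects `sample_id`, `label`.
#'
#' @param path TSV file path.
#' @param mode `"survival"` or `"binary"`.
#' @return A [survival_outcome()] or [binary_outcome()].
#' @export
read_outcome <- function(path, mode = c("survival", "binary")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (mode == "survival") {
    need <- c("sample_id", "time", "event")
    if (!all(need %in% colnames(df)))
      stop("survival outcome needs columns: ", paste(need, collapse = ", "))
    ev <- df$event
    if (!all(ev %in% c(0, 1, "0", "1", TRUE, FALSE)))
      stop("event column not coercible to {0,1}")
    survival_outcome(df$sample_id, df$time, as.integer(ev) == 1L)
  } else {
    need <- c("sample_id", "label")
    if (!all(need %in% colnames(df)))
      stop("binary outcome needs columns: ", paste(need, collapse = ", "))
    lab <- df$label
    if (!all(lab %in% c(0, 1, "0", "1", TRUE, FALSE)))
      stop("label column not coercible to {0,1}")
    binary_outcome(df$sample_id, as.integer(lab) == 1L)
  }
}

#' Read a clinical covariate table from TSV
#'
#' Recognised columns: `sample_id`, `age_at_diagnosis`, `ajcc_stage`,
#' `er_status`, `pr_status`, `her2_status`, `node_status`. Blank or missing
#' categorical entries become `"unknown"`; unknown levels are kept verbatim.
#' Extra columns are preserved as-is (categorical unless numeric).
#'
#' @param path TSV file path.
#' @return A data frame of class `clinical_table` with one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(df)) stop("clinical table needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  if ("age_at_diagnosis" %in% colnames(df)) {
    df$age_at_diagnosis <- as.numeric(df$age_at_diagnosis)
    if (any(df$age_at_diagnosis < 0, na.rm = TRUE)) stop("negative age")
  }
  for (col in setdiff(colnames(df), c("sample_id", "age_at_diagnosis"))) {
    if (!is.numeric(df[[col]])) {
      x <- as.character(df[[col]])
      x[is.na(x) | !nzchar(trimws(x))] <- "unknown"
      df[[col]] <- x
    }
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a BED-like feature annotation table
#'
#' Tab-separated columns `feature_id`, `chrom`, `position` (1-based),
#' `nearest_gene` (may be empty).
#'
#' @param path TSV file path.
#' @return A data frame with one row per feature.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA"))
  need <- c("feature_id", "chrom", "position")
  if (!all(need %in% colnames(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in annotation")
  df$position <- as.integer(df$position)
  if (any(is.na(df$position)) || any(df$position < 1))
    stop("annotation positions must be integers >= 1 (1-based)")
  if (!"nearest_gene" %in% colnames(df)) df$nearest_gene <- ""
  df$nearest_gene[is.na(df$nearest_gene)] <- ""
  df[, c("feature_id", "chrom", "position", "nearest_gene")]
}

#' Read gene sets from GMT or plain text
#'
#' GMT: one set per line, tab-separated `name`, `description`, genes.
#' Plain: one gene per line; the whole file is one set named after the file.
#'
#' @param path File path.
#' @param format `"gmt"` or `"plain"`.
#' @return A named list of character vectors (unique gene ids per set).
#' @export
read_gene_sets <- function(path, format = c("gmt", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "plain") {
    genes <- unique(trimws(lines))
    if (!length(genes)) stop("empty gene list: ", path)
    sets <- list(genes)
    names(sets) <- sub("\\.[^.]*$", "", basename(path))
    return(sets)
  }
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(ln, 1, 40))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT set with no genes: ", parts[1])
    sets[[parts[1]]] <- genes
  }
  sets
}

#' Intersect and co-order samples across inputs
#'
#' Restricts matrices, the clinical table and the outcome to their common
#' samples, all in one identical order (order of appearance in the first
#' matrix). Dropped sample counts are reported via `message()`.
#'
#' @param matrices A list of [omics_matrix()] objects (at least one).
#' @param clinical Optional `clinical_table`.
#' @param outcome Optional `survival_outcome` or `binary_outcome`.
#' @return A list with elements `matrices`, `clinical`, `outcome` and
#'   `sample_ids` (the shared order).
#' @export
align_samples <- function(matrices, clinical = NULL, outcome = NULL) {
  if (inherits(matrices, "omics_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  shared <- matrices[[1]]$sample_ids
  for (m in matrices[-1]) shared <- shared[shared %in% m$sample_ids]
  if (!is.null(clinical)) shared <- shared[shared %in% clinical$sample_id]
  if (!is.null(outcome)) shared <- shared[shared %in% outcome$sample_ids]
  if (!length(shared)) stop("no samples shared across inputs")
  n_drop <- sum(vapply(matrices, function(m) length(m$sample_ids), 1L) -
                  length(shared))
  if (n_drop > 0)
    message(sprintf("align_samples: %d non-shared sample entries dropped", n_drop))
  out <- list(
    matrices = lapply(matrices, subset_omics, samples = shared),
    clinical = if (!is.null(clinical))
      clinical[match(shared, clinical$sample_id), , drop = FALSE],
    outcome = if (!is.null(outcome)) subset_outcome(outcome, shared),
    sample_ids = shared)
  if (!is.null(out$clinical)) rownames(out$clinical) <- NULL
  out
}
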