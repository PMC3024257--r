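#' Expression matrix with detection flags and sample metadata
#'
#' The substrate of every pipeline stage: a features x samples matrix of
#' log2 expression values, a logical detection-flag matrix of the same
#' shape (microarray Present/Absent calls, or any per-cell QC flag), and
#' per-sample metadata (`sample_id`, `dataset_id`, `disease_status`,
#' `group`). Values are assumed already normalized (e.g. GCRMA log2);
#' low-level normalization is out of scope.
#'
#' @param values numeric matrix (features x samples) with rownames
#'   (feature ids) and colnames (sample ids); all values finite.
#' @param detected logical matrix of the same shape; `NULL` means
#'   all-detected.
#' @param sample_meta data.frame with columns `sample_id`, `dataset_id`,
#'   `disease_status`, `group` (one of `"case"`, `"control"`, `"other"`);
#'   `NULL` fills defaults (single dataset, all `"other"`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, detected = NULL, sample_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_coexmod("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_coexmod("`values` must have feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop_coexmod("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop_coexmod("duplicate sample ids")
  if (!all(is.finite(values))) stop_coexmod("`values` must be finite")
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!identical(dim(detected), dim(values))) {
    stop_coexmod("`detected` must have the same shape as `values`")
  }
  mode(detected) <- "logical"
  dimnames(detected) <- dimnames(values)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(
      sample_id = colnames(values),
      dataset_id = "dataset1",
      disease_status = "none",
      group = "other",
      stringsAsFactors = FALSE
    )
  }
  required <- c("sample_id", "dataset_id", "disease_status", "group")
  if (!all(required %in% names(sample_meta))) {
    stop_coexmod("`sample_meta` needs columns: ", paste(required, collapse = ", "))
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id),
                             required, drop = FALSE]
  if (anyNA(sample_meta$sample_id)) {
    stop_coexmod("`sample_meta` must cover every sample id")
  }
  if (!all(sample_meta$group %in% c("case", "control", "other"))) {
    stop_coexmod("`group` must be one of case/control/other")
  }
  rownames(sample_meta) <- NULL
  structure(
    list(values = values, detected = detected, sample_meta = sample_meta),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d features x %d samples (%d datasets; %d cases, %d controls)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$sample_meta$dataset_id)),
    sum(x$sample_meta$group == "case"),
    sum(x$sample_meta$group == "control")
  ))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

# Subset an expression_matrix by feature/sample index or name.
em_subset <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  d <- m$detected
  meta <- m$sample_meta
  if (!is.null(features)) {
    v <- v[features, , drop = FALSE]
    d <- d[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    d <- d[, samples, drop = FALSE]
    meta <- meta[match(colnames(v), meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(values = v, detected = d, sample_meta = meta),
            class = "expression_matrix")
}

#' Standardize an expression matrix along one axis
#'
#' Centers and scales each gene (row) or sample (column) vector to mean 0
#' and standard deviation 1 (denominator n-1). Used before computing
#' weighted module sample scores and inside the ISA double normalization.
#'
#' @param m an [expression_matrix()].
#' @param axis `"per-gene"` (rows) or `"per-sample"` (columns).
#' @return An `expression_matrix` with standardized values; detection
#'   flags and metadata carried through.
#' @export
standardize <- function(m, axis = c("per-gene", "per-sample")) {
  axis <- match.arg(axis)
  v <- m$values
  z <- standardize_matrix(v, margin = if (axis == "per-gene") 1L else 2L)
  out <- m
  out$values <- z
  out
}

standardize_matrix <- function(v, margin) {
  if (margin == 2L) return(t(standardize_matrix(t(v), 1L)))
  mu <- rowMeans(v)
  ctr <- v - mu
  sds <- sqrt(rowSums(ctr^2) / (ncol(v) - 1L))
  bad <- !is.finite(sds) | sds == 0
  if (any(bad)) {
    stop_coexmod("constant vector(s), cannot standardize: ",
                 paste(utils::head(rownames(v)[bad], 5), collapse = ", "))
  }
  ctr / sds
}
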