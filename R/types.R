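#' @keywords internal
"_PACKAGE"

SAMPLE_TYPES <- c("monocyte", "pbmc", "whole_blood", "other")

#' Probe-level case-control expression dataset
#'
#' Container for one cohort's probe-by-sample expression matrix together with
#' its case/control labels, platform identifier and sample-type tag
#' (monocyte, PBMC, whole blood, ...). This is the form in which GEO
#' series-matrix-like files are held before probe collapse.
#'
#' @param dataset_id Character scalar naming the cohort (e.g. a GEO accession).
#' @param platform_id Character scalar naming the array platform.
#' @param sample_type One of `"monocyte"`, `"pbmc"`, `"whole_blood"`, `"other"`.
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param labels Character or factor vector of `"case"`/`"control"`, one per
#'   sample, named by sample id or in column order.
#' @return An object of class `expr_dataset`.
#' @export
expr_dataset <- function(dataset_id, platform_id, sample_type, values, labels) {
  sample_type <- match.arg(sample_type, SAMPLE_TYPES)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id in expression matrix")
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("sample(s) missing from label assignment: ",
           paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("one label per sample required")
  if (anyNA(labels) || !all(labels %in% c("case", "control")))
    stop("labels must be 'case' or 'control' with no missing values")
  if (length(unique(labels)) < 2L)
    stop("need both classes: dataset has only '", labels[1], "' samples")
  structure(
    list(dataset_id = dataset_id, platform_id = platform_id,
         sample_type = sample_type, values = values,
         labels = stats::setNames(labels, colnames(values))),
    class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %s [%s, %s]: %d probes x %d samples (%d case / %d control)\n",
              x$dataset_id, x$platform_id, x$sample_type,
              nrow(x$values), ncol(x$values),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Probe-to-gene-symbol annotation for one platform
#'
#' @param platform_id Character scalar.
#' @param map Named character vector: names are probe ids, values are official
#'   gene symbols (upper-cased on construction). Probes with no symbol are
#'   simply absent.
#' @return An object of class `probe_map`.
#' @export
probe_map <- function(platform_id, map) {
  map <- stats::setNames(toupper(as.character(map)), names(map))
  if (anyDuplicated(names(map))) stop("duplicate probe id in probe map")
  if (any(!nzchar(map))) stop("empty gene symbol in probe map")
  structure(list(platform_id = platform_id, map = map), class = "probe_map")
}

#' Gene-by-sample expression matrix on a known scale
#'
#' The post-collapse representation of a cohort: one row per gene symbol,
#' case/control labels retained, with an explicit scale flag. All marginal
#' statistics require `scale == "log2"`; [ensure_log_scale()] establishes it.
#'
#' @param dataset_id,sample_type As in [expr_dataset()].
#' @param values Numeric matrix, genes x samples, rownames = gene symbols.
#' @param labels `"case"`/`"control"` per sample.
#' @param scale `"log2"` (default) or `"as_loaded"` when not yet verified.
#' @param transformed Logical: was a log2 transform applied on ingest?
#' @return An object of class `gene_matrix`.
#' @export
gene_matrix <- function(dataset_id, sample_type, values, labels,
                        scale = "log2", transformed = FALSE) {
  sample_type <- match.arg(sample_type, SAMPLE_TYPES)
  scale <- match.arg(scale, c("log2", "as_loaded"))
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("values must have gene-symbol rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbol")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(values),
            all(labels %in% c("case", "control")))
  structure(
    list(dataset_id = dataset_id, sample_type = sample_type, values = values,
         labels = labels, scale = scale, transformed = transformed),
    class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %s [%s, %s]: %d genes x %d samples\n",
              x$dataset_id, x$sample_type, x$scale,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' The genes one method selected from one dataset
#'
#' @param dataset_id Cohort id.
#' @param method One of `"fc_top_k"`, `"t_top_k"`, `"fdr_threshold"`, `"lasso"`.
#' @param genes Character vector of selected gene symbols.
#' @param params Named list of the method parameters used (k, alpha, lambda...).
#' @return An object of class `selection_set`.
#' @export
selection_set <- function(dataset_id, method, genes, params = list()) {
  method <- match.arg(method, c("fc_top_k", "t_top_k", "fdr_threshold", "lasso"))
  structure(list(dataset_id = dataset_id, method = method,
                 genes = unique(as.character(genes)), params = params),
            class = "selection_set")
}

#' @export
print.selection_set <- function(x, ...) {
  cat(sprintf("<selection_set> %s / %s: %d genes\n",
              x$dataset_id, x$method, length(x$genes)))
  invisible(x)
}
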