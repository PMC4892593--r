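# File readers/writers. Every external format the pipeline touches comes
# through here; downstream modules only see the domain types in types.R.
# Canonical dialect is plain TSV with a header row; GEO series-matrix style
# preambles ("!"-prefixed lines) are skipped on read.

read_tsv_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!startsWith(lines, "!") & nzchar(lines)]
}

#' Read a probe-level expression table
#'
#' Expects a tab-separated file whose first column holds probe ids and whose
#' remaining columns hold one sample each, with sample ids in the first row.
#' Lines beginning with `!` (GEO series-matrix preamble) are ignored.
#'
#' @param path Path to the TSV file.
#' @param dataset_id,platform_id,sample_type Metadata for the cohort.
#' @param labels Case/control assignment: a named character vector of
#'   `"case"`/`"control"` keyed by sample id, or a path to a two-column TSV
#'   (sample_id, label) as read by [read_labels()].
#' @return An [expr_dataset()].
#' @export
read_expression_table <- function(path, dataset_id, platform_id = "unknown",
                                  sample_type = "other", labels) {
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("expression table needs a header and data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(body) != length(header)))
    stop("ragged row(s) in expression table")
  probe_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(length(sample_ids))))
  if (length(sample_ids) == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) stop("non-numeric expression value(s) in ", path)
  values <- t(matrix(vals, nrow = length(sample_ids),
                     dimnames = list(sample_ids, probe_ids)))
  expr_dataset(dataset_id, platform_id, sample_type, values, labels)
}

#' Write a probe-level expression table
#'
#' Inverse of [read_expression_table()]: full-precision TSV so that a
#' write/read round trip reproduces the matrix bit-exactly.
#'
#' @param ds An [expr_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(ds$values)), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(ds$values)), function(i)
    paste(c(rownames(ds$values)[i], sprintf("%.17g", ds$values[i, ])),
          collapse = "\t"), "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a sample label assignment
#'
#' Two-column TSV (with header) mapping sample id to `case` or `control`.
#'
#' @param path Path to the TSV file.
#' @return Named character vector of labels keyed by sample id.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stop("label file needs columns sample_id, label")
  lab <- tolower(df[[2]])
  if (!all(lab %in% c("case", "control")))
    stop("labels must be 'case' or 'control'")
  stats::setNames(lab, df[[1]])
}

#' Write a sample label assignment
#' @param ds An [expr_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(ds, path) {
  utils::write.table(
    data.frame(sample_id = names(ds$labels), label = unname(ds$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Two-column TSV (with header) of probe id and official gene symbol. Rows
#' with a blank or `NA` symbol are skipped; symbols are upper-cased. A probe
#' listed twice with the same symbol is tolerated; conflicting duplicates are
#' an error.
#'
#' @param path Path to the TSV file.
#' @param platform_id Platform the annotation belongs to.
#' @return A [probe_map()].
#' @export
read_probe_map <- function(path, platform_id) {
  lines <- read_tsv_lines(path)
  if (length(lines) <= 1L)
    return(probe_map(platform_id, character(0)))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  probe <- vapply(parts, `[[`, "", 1L)
  sym <- toupper(trimws(vapply(parts, function(p)
    if (length(p) >= 2L) p[[2]] else "", "")))
  keep <- nzchar(sym) & sym != "NA"
  probe <- probe[keep]; sym <- sym[keep]
  if (anyDuplicated(probe)) {
    per_probe <- tapply(sym, probe, function(s) length(unique(s)))
    if (any(per_probe > 1L))
      stop("conflicting annotation for probe(s): ",
           paste(names(per_probe)[per_probe > 1L], collapse = ", "))
    first <- !duplicated(probe)
    probe <- probe[first]; sym <- sym[first]
  }
  probe_map(platform_id, stats::setNames(sym, probe))
}

#' Read a reported per-gene statistics table
#'
#' Loads a long-format TSV of per-dataset gene statistics (columns `gene`,
#' `dataset_id`, `sample_type`, `fc_ratio`, optionally `p_value`, `q_value`)
#' into one `marginal_stats` table per dataset, ready for
#' [marker_report()]. This is how externally reported statistics — e.g. the
#' published fold changes of a marker panel across GEO cohorts — enter the
#' package (see `system.file("extdata", "sle_marker_stats_published.tsv",
#' package = "crossmarker")`).
#'
#' @param path Path to the TSV file.
#' @return Named list of `marginal_stats` tables, keyed by dataset id.
#' @export
read_marker_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "dataset_id", "sample_type", "fc_ratio")
  if (!all(need %in% names(df)))
    stop("marker stats table needs columns: ", paste(need, collapse = ", "))
  df$gene <- toupper(df$gene)
  if (!"fc_magnitude" %in% names(df))
    df$fc_magnitude <- pmax(df$fc_ratio, 1 / df$fc_ratio)
  lapply(split(df, df$dataset_id)[unique(df$dataset_id)], function(d)
    as_marginal_stats(d[setdiff(names(d), c("dataset_id", "sample_type"))],
                      d$dataset_id[1], d$sample_type[1]))
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' term id, description, then member gene symbols. Duplicate genes within a
#' line are counted once; symbols are upper-cased.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors keyed by term id) and `term_names` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 columns")
  ids <- vapply(parts, `[[`, "", 1L)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  structure(
    list(sets = stats::setNames(sets, ids),
         term_names = stats::setNames(vapply(parts, `[[`, "", 2L), ids)),
    class = "gene_set_collection")
}

#' Read an undirected protein-protein interaction edge list
#'
#' TSV with header and columns gene_a, gene_b, then optionally an evidence
#' tag and a confidence score in \[0, 1\]. Edges are deduplicated ignoring
#' orientation; self-loops are dropped (their count is kept as attribute
#' `n_self_loops` and reported with a warning).
#'
#' @param path Path to the TSV file.
#' @return A `ppi_graph`: data frame with columns `gene_a`, `gene_b`,
#'   `evidence`, `score`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  a <- toupper(df[[1]]); b <- toupper(df[[2]])
  evidence <- if (ncol(df) >= 3L) df[[3]] else rep(NA_character_, length(a))
  score <- if (ncol(df) >= 4L) as.numeric(df[[4]]) else rep(NA_real_, length(a))
  if (any(!is.na(score) & (score < 0 | score > 1)))
    stop("interaction score outside [0, 1]")
  loops <- a == b
  if (any(loops))
    warning(sum(loops), " self-loop(s) dropped")
  a2 <- pmin(a, b); b2 <- pmax(a, b)  # canonical orientation for dedup
  keep <- !loops & !duplicated(paste(a2, b2, sep = "\r"))
  out <- data.frame(gene_a = a2[keep], gene_b = b2[keep],
                    evidence = evidence[keep], score = score[keep],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ppi_graph", "data.frame"),
            n_self_loops = sum(loops))
}
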