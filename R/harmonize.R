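# Probe-to-gene collapse and cross-cohort gene harmonisation: every cohort
# is reduced to official gene symbols, brought onto the log2 scale, and
# restricted to the genes profiled in all cohorts.

#' Collapse probe rows to gene rows
#'
#' Probes without an annotation are dropped. For genes measured by several
#' probes, `max_mean_probe` (the default, a common microarray convention)
#' keeps the probe row with the highest mean across all samples, breaking
#' ties by probe id; `mean_of_probes` averages the probe rows. Output genes
#' are in lexicographic order, making the result independent of the input
#' probe order.
#'
#' @param ds An [expr_dataset()].
#' @param pmap A [probe_map()] for the same platform.
#' @param rule `"max_mean_probe"` or `"mean_of_probes"`.
#' @return A [gene_matrix()] with `scale = "as_loaded"`.
#' @export
collapse_probes <- function(ds, pmap, rule = c("max_mean_probe", "mean_of_probes")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ds, "expr_dataset"), inherits(pmap, "probe_map"))
  if (!identical(ds$platform_id, pmap$platform_id))
    stop("platform mismatch: dataset is ", ds$platform_id,
         ", probe map is ", pmap$platform_id)
  probes <- intersect(rownames(ds$values), names(pmap$map))
  if (!length(probes)) stop("no annotated probes in dataset ", ds$dataset_id)
  vals <- ds$values[probes, , drop = FALSE]
  sym <- unname(pmap$map[probes])
  if (rule == "max_mean_probe") {
    m <- rowMeans(vals)
    ord <- order(sym, -m, probes)   # per gene: highest mean, tie -> probe id
    pick <- ord[!duplicated(sym[ord])]
    out <- vals[pick, , drop = FALSE]
    rownames(out) <- sym[pick]
  } else {
    out <- rowsum(vals, sym) / as.vector(table(sym)[sort(unique(sym))])
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  gene_matrix(ds$dataset_id, ds$sample_type, out, ds$labels,
              scale = "as_loaded")
}

#' Establish the log2 scale of a gene matrix
#'
#' Heuristic: processed microarray matrices on the log2 scale rarely exceed
#' ~16, while linear intensities run into the thousands. If the maximum value
#' exceeds 50 the matrix is taken to be linear and replaced by
#' `log2(x + 1)` (and flagged `transformed`); otherwise it passes through
#' unchanged. Negative values alongside a maximum above 50 are ambiguous and
#' raise an error.
#'
#' @param gm A [gene_matrix()].
#' @return The matrix with `scale = "log2"`.
#' @export
ensure_log_scale <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  mx <- max(gm$values)
  if (mx > 50) {
    if (min(gm$values) < 0)
      stop("ambiguous scale: negative values with max ", format(mx))
    gm$values <- log2(gm$values + 1)
    gm$transformed <- TRUE
  }
  gm$scale <- "log2"
  gm
}

#' Restrict cohorts to their commonly profiled genes
#'
#' @param gms List of >= 2 [gene_matrix()] objects.
#' @return List with `matrices` (each restricted to the intersection, rows in
#'   identical lexicographic order) and `common_genes`.
#' @export
intersect_genes <- function(gms) {
  stopifnot(length(gms) >= 2L,
            all(vapply(gms, inherits, TRUE, "gene_matrix")))
  common <- sort(Reduce(intersect, lapply(gms, function(g) rownames(g$values))))
  if (!length(common))
    stop("no genes common to all ", length(gms), " cohorts")
  list(matrices = lapply(gms, function(g) {
         g$values <- g$values[common, , drop = FALSE]
         g
       }),
       common_genes = common)
}
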