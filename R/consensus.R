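# Cross-dataset consensus: vote counting per method, the m-of-n filter,
# the marginal/joint pool combination yielding the common markers, and the
# per-gene per-dataset report with fold-change ranges by sample type.

#' Count per-method dataset votes for each gene
#'
#' @param selections List of [selection_set()]s (any mix of methods and
#'   datasets; each (method, dataset) pair must appear at most once).
#' @return A `vote_table`: list with `counts` (per method, a named integer
#'   vector gene -> number of distinct datasets selecting it) and
#'   `n_datasets` (per method, how many datasets contributed).
#' @export
count_votes <- function(selections) {
  stopifnot(length(selections) >= 1L,
            all(vapply(selections, inherits, TRUE, "selection_set")))
  keys <- vapply(selections, function(s) paste(s$method, s$dataset_id, sep = "/"), "")
  if (anyDuplicated(keys))
    stop("duplicate selection for ", keys[duplicated(keys)][1])
  methods <- unique(vapply(selections, `[[`, "", "method"))
  counts <- n_datasets <- list()
  for (m in methods) {
    sel <- selections[vapply(selections, `[[`, "", "method") == m]
    tab <- table(unlist(lapply(sel, `[[`, "genes")))
    counts[[m]] <- stats::setNames(as.integer(tab), names(tab))
    n_datasets[[m]] <- length(sel)
  }
  structure(list(counts = counts, n_datasets = n_datasets),
            class = "vote_table")
}

#' Keep genes selected in at least m of the n datasets
#'
#' @param votes A `vote_table` from [count_votes()].
#' @param method Which method's votes to filter.
#' @param m Minimum number of datasets (default 3).
#' @return Character vector of gene symbols (sorted).
#' @export
m_of_n_filter <- function(votes, method, m = 3L) {
  stopifnot(inherits(votes, "vote_table"), m >= 1L)
  if (!method %in% names(votes$counts))
    stop("no selections for method '", method, "'")
  n <- votes$n_datasets[[method]]
  if (m > n)
    stop("m = ", m, " exceeds the ", n, " datasets available for ", method)
  cnt <- votes$counts[[method]]
  sort(names(cnt)[cnt >= m])
}

#' Combine the marginal pool and the joint pool into common markers
#'
#' The marginal pool is the union of the (post m-of-n) gene sets of the
#' marginal methods; the common markers are its intersection with the joint
#' (lasso) pool. The inclusion-exclusion identity
#' `|A u B| = |A| + |B| - |A n B|` is asserted on every call.
#'
#' @param marginal_sets Named list of character vectors, one per marginal
#'   method (post consensus filter).
#' @param joint_pool Character vector: the joint-analysis consensus genes.
#' @return List with `marginal_sets`, `marginal_pool`, `joint_pool`,
#'   `common_markers`, `all_selected` (the union) and their sizes.
#' @export
combine_pools <- function(marginal_sets, joint_pool) {
  stopifnot(is.list(marginal_sets))
  marginal_pool <- sort(unique(unlist(marginal_sets, use.names = FALSE)))
  joint_pool <- sort(unique(as.character(joint_pool)))
  common <- intersect(marginal_pool, joint_pool)
  all_selected <- union(marginal_pool, joint_pool)
  stopifnot(length(all_selected) ==
              length(marginal_pool) + length(joint_pool) - length(common))
  list(marginal_sets = marginal_sets,
       marginal_pool = marginal_pool,
       joint_pool = joint_pool,
       common_markers = sort(common),
       all_selected = all_selected,
       sizes = c(marginal_pool = length(marginal_pool),
                 joint_pool = length(joint_pool),
                 common_markers = length(common),
                 all_selected = length(all_selected)))
}

#' Per-marker, per-dataset statistics report with FC ranges by sample type
#'
#' Builds the long table of fold change, p and q for each marker in each
#' dataset, optionally flagging which selection methods picked it where, and
#' summarises min-max linear fold change per sample type over a chosen gene
#' subset (e.g. an interferon-signature subset), which is how attenuation of
#' an effect from monocyte to PBMC to whole blood is usually quoted.
#'
#' @param markers Character vector of marker gene symbols.
#' @param stats_list List of `marginal_stats` tables, one per dataset (each
#'   carrying `dataset_id` and `sample_type` attributes). Every marker must
#'   be present in every table.
#' @param selections Optional list of [selection_set()]s used to add
#'   logical `sel_<method>` columns.
#' @param range_genes Gene subset for the FC range summary (default: all
#'   `markers`).
#' @return List with `per_gene_stats` (long data frame) and `fc_ranges`
#'   (data frame `sample_type`, `fc_min`, `fc_max`).
#' @export
marker_report <- function(markers, stats_list, selections = NULL,
                          range_genes = markers) {
  stopifnot(length(markers) >= 1L,
            all(vapply(stats_list, inherits, TRUE, "marginal_stats")))
  rows <- lapply(stats_list, function(st) {
    ds <- attr(st, "dataset_id")
    miss <- setdiff(markers, st$gene)
    if (length(miss))
      stop("marker(s) missing from ", ds, " statistics: ",
           paste(miss, collapse = ", "))
    idx <- match(markers, st$gene)
    out <- data.frame(gene = markers, dataset_id = ds,
                      sample_type = attr(st, "sample_type"),
                      fc_ratio = st$fc_ratio[idx],
                      stringsAsFactors = FALSE)
    for (col in c("fc_magnitude", "t_stat", "p_value", "q_value"))
      if (col %in% names(st)) out[[col]] <- st[[col]][idx]
    out
  })
  per_gene <- do.call(rbind, rows)
  rownames(per_gene) <- NULL
  if (!is.null(selections)) {
    for (m in unique(vapply(selections, `[[`, "", "method"))) {
      sel <- selections[vapply(selections, `[[`, "", "method") == m]
      picked <- lapply(stats::setNames(sel, vapply(sel, `[[`, "", "dataset_id")),
                       `[[`, "genes")
      per_gene[[paste0("sel_", m)]] <- mapply(
        function(g, d) !is.null(picked[[d]]) && g %in% picked[[d]],
        per_gene$gene, per_gene$dataset_id)
    }
  }
  sub <- per_gene[per_gene$gene %in% range_genes, , drop = FALSE]
  fc_ranges <- do.call(rbind, lapply(split(sub, sub$sample_type), function(g)
    data.frame(sample_type = g$sample_type[1],
               fc_min = min(g$fc_ratio), fc_max = max(g$fc_ratio),
               stringsAsFactors = FALSE)))
  rownames(fc_ranges) <- NULL
  list(per_gene_stats = per_gene, fc_ranges = fc_ranges)
}

#' Format a marker report table for display
#'
#' Rounds fold changes to 2 decimals and p/q to 2 significant figures in
#' scientific notation (full precision stays in the unformatted table).
#'
#' @param per_gene_stats The long table from [marker_report()].
#' @return Data frame of formatted character columns.
#' @export
format_marker_table <- function(per_gene_stats) {
  out <- per_gene_stats
  out$fc_ratio <- sprintf("%.2f", out$fc_ratio)
  for (col in intersect(c("p_value", "q_value"), names(out)))
    out[[col]] <- sprintf("%.2e", out[[col]])
  out
}
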