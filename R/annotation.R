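# Offline functional annotation of a marker set: hypergeometric gene-set
# over-representation against a user-supplied GMT, and a cross-set
# interaction summary over a local PPI edge list (no web services).

#' Gene-set over-representation by the hypergeometric test
#'
#' For each term, with universe size N, term size K (after intersecting the
#' term with the universe), study size n and overlap k, the p-value is the
#' upper tail `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`; terms with zero
#' overlap get p = 1. q-values are Benjamini-Hochberg across the tested
#' terms.
#'
#' @param study Character vector of study genes (must lie in `universe`).
#' @param universe Character vector: the gene universe (e.g. the commonly
#'   profiled genes).
#' @param gsc A `gene_set_collection` from [read_gmt()].
#' @return Data frame with one row per term: `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `p_value`, `q_value`, `overlap_genes`; sorted by p.
#' @export
enrich <- function(study, universe, gsc) {
  study <- unique(toupper(study)); universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(study, universe)
  if (length(extra))
    stop("study gene(s) not in universe: ", paste(extra, collapse = ", "))
  stopifnot(inherits(gsc, "gene_set_collection"))
  N <- length(universe); n <- length(study)
  rows <- lapply(names(gsc$sets), function(id) {
    term <- intersect(gsc$sets[[id]], universe)
    K <- length(term)
    ov <- intersect(term, study)
    k <- length(ov)
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = unname(gsc$term_names[id]),
               k = k, n = n, K = K, N = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$term_id),
             c("term_id", "term_name", "k", "n", "K", "N",
               "p_value", "q_value", "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' Interactions of a marker set with itself and a second gene set
#'
#' Splits the edges of a PPI graph by membership: edges within set A (e.g.
#' the common markers), edges linking A to B (e.g. GWAS susceptibility
#' genes), and the members of A that are isolated — degree 0 in the subgraph
#' induced by A union B (genes absent from the graph are degree 0).
#'
#' @param g A `ppi_graph` from [read_edge_list()].
#' @param set_a,set_b Character vectors of gene symbols.
#' @return A `cross_set_report`: list with `within_a` and `a_to_b` edge data
#'   frames and `isolated` (sorted character vector).
#' @export
cross_set_interactions <- function(g, set_a, set_b) {
  stopifnot(inherits(g, "ppi_graph"))
  set_a <- unique(toupper(set_a)); set_b <- unique(toupper(set_b))
  in_a <- g$gene_a %in% set_a & g$gene_b %in% set_a
  ab <- (g$gene_a %in% set_a & g$gene_b %in% set_b) |
        (g$gene_b %in% set_a & g$gene_a %in% set_b)
  both <- union(set_a, set_b)
  sub <- g[g$gene_a %in% both & g$gene_b %in% both, , drop = FALSE]
  isolated <- if (nrow(sub)) {
    ig <- igraph::graph_from_data_frame(sub[, c("gene_a", "gene_b")],
                                        directed = FALSE, vertices = both)
    sort(intersect(names(which(igraph::degree(ig) == 0)), set_a))
  } else sort(set_a)
  structure(list(within_a = as.data.frame(g[in_a, , drop = FALSE]),
                 a_to_b = as.data.frame(g[ab & !in_a, , drop = FALSE]),
                 isolated = isolated),
            class = "cross_set_report")
}

#' @export
print.cross_set_report <- function(x, ...) {
  cat(sprintf("<cross_set_report> %d edges within A, %d A-to-B, isolated: %s\n",
              nrow(x$within_a), nrow(x$a_to_b),
              if (length(x$isolated)) paste(x$isolated, collapse = ", ") else "none"))
  invisible(x)
}
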