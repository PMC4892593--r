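# End-to-end orchestration: harmonise -> marginal selection (3 methods per
# dataset) -> joint lasso selection -> consensus voting -> common markers,
# with optional on-disk artifacts and a run manifest.

#' Configure a consensus pipeline run
#'
#' @param top_k Genes kept by each top-k ranking (default 100).
#' @param fdr_alpha FDR selection level (default 0.001).
#' @param m_required Minimum datasets a gene must be selected in (default 3).
#' @param fc_rank_mode `"magnitude"` (two-sided) or `"ratio"` (up-regulation
#'   only) for the FC ranking.
#' @param t_variant `"welch"` or `"student"`.
#' @param collapse_rule Probe-collapse rule, see [collapse_probes()].
#' @param joint_mode How per-cohort lasso selections aggregate into the
#'   joint pool: `"pooled"` (union over datasets; default) or `"consensus"`
#'   (the same m-of-n filter as the marginal methods). The union is the
#'   default because a cross-validated lasso is a sparse model selector, not
#'   a per-gene test: in any single cohort a true marker is routinely
#'   shadowed by a correlated neighbour or squeezed out by a small sample
#'   (a 5-vs-5 cohort supports at most ~9 nonzero coefficients), so
#'   demanding simultaneous selection in m cohorts discards most true
#'   markers; false positives are instead controlled by the final
#'   intersection with the marginal consensus pool.
#' @param lasso A [lasso_config()].
#' @param seed Top-level seed; per-dataset lasso fold seeds are forked from
#'   it deterministically.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(top_k = 100L, fdr_alpha = 0.001, m_required = 3L,
                            fc_rank_mode = c("magnitude", "ratio"),
                            t_variant = c("welch", "student"),
                            collapse_rule = c("max_mean_probe", "mean_of_probes"),
                            joint_mode = c("pooled", "consensus"),
                            lasso = lasso_config(), seed = 1L) {
  stopifnot(top_k >= 1L, fdr_alpha > 0, fdr_alpha <= 1, m_required >= 1L)
  structure(list(top_k = as.integer(top_k), fdr_alpha = fdr_alpha,
                 m_required = as.integer(m_required),
                 fc_rank_mode = match.arg(fc_rank_mode),
                 t_variant = match.arg(t_variant),
                 collapse_rule = match.arg(collapse_rule),
                 joint_mode = match.arg(joint_mode),
                 lasso = lasso, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full cross-dataset consensus pipeline
#'
#' Collapses probes to gene symbols per cohort, restricts all cohorts to the
#' commonly profiled genes, computes marginal statistics and the three
#' marginal selections per cohort, runs the joint lasso selection per cohort,
#' applies the m-of-n consensus vote per method, and intersects the marginal
#' pool with the joint pool to obtain the common markers.
#'
#' @param datasets List of >= 2 [expr_dataset()]s.
#' @param probe_maps List of [probe_map()]s, either named by platform id or
#'   matching `datasets` positionally.
#' @param cfg An [analysis_config()].
#' @param out_dir Optional directory; when given, all per-dataset statistics,
#'   selections, the consensus and a run manifest are written there.
#' @param quiet Suppress the stage accounting printed to stderr.
#' @return A `consensus_result`: list with `votes`, `marginal_sets`,
#'   `marginal_pool`, `joint_pool`, `common_markers`, `all_selected`,
#'   `sizes`, `per_gene_stats`, `fc_ranges`, `stats` (per-dataset marginal
#'   tables), `selections`, `common_genes` and `config`.
#' @export
run_pipeline <- function(datasets, probe_maps, cfg = analysis_config(),
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(length(datasets) >= 2L,
            all(vapply(datasets, inherits, TRUE, "expr_dataset")))
  if (cfg$m_required > length(datasets))
    stop("m_required = ", cfg$m_required, " exceeds the ",
         length(datasets), " datasets supplied")
  say <- function(...) if (!quiet) message(sprintf(...))

  if (is.null(names(probe_maps)))
    names(probe_maps) <- vapply(probe_maps, `[[`, "", "platform_id")
  gms <- lapply(datasets, function(ds) {
    pm <- probe_maps[[ds$platform_id]]
    if (is.null(pm)) stop("no probe map for platform ", ds$platform_id,
                          " (dataset ", ds$dataset_id, ")")
    gm <- ensure_log_scale(collapse_probes(ds, pm, cfg$collapse_rule))
    say("[harmonize] %s: %d probes -> %d genes", ds$dataset_id,
        nrow(ds$values), nrow(gm$values))
    gm
  })
  harm <- intersect_genes(gms)
  gms <- harm$matrices
  say("[harmonize] %d genes common to all %d datasets",
      length(harm$common_genes), length(gms))

  stats_list <- lapply(gms, marginal_stats, t_variant = cfg$t_variant)
  marg_sel <- list()
  for (st in stats_list) {
    marg_sel <- c(marg_sel, list(
      select_top_k(st, "fc", cfg$top_k, cfg$fc_rank_mode),
      select_top_k(st, "t_p", cfg$top_k),
      select_fdr(st, cfg$fdr_alpha)))
  }
  joint_sel <- lapply(seq_along(gms), function(i) {
    lcfg <- cfg$lasso
    lcfg$seed <- fork_seed(cfg$seed, 5000L + i)
    s <- lasso_select(gms[[i]], lcfg)
    say("[lasso] %s: %d genes at lambda = %.4g", s$dataset_id,
        length(s$genes), s$params$lambda)
    s
  })

  votes <- count_votes(c(marg_sel, joint_sel))
  marginal_sets <- lapply(
    stats::setNames(nm = c("fc_top_k", "t_top_k", "fdr_threshold")),
    function(m) m_of_n_filter(votes, m, cfg$m_required))
  joint_pool <- if (cfg$joint_mode == "consensus")
    m_of_n_filter(votes, "lasso", cfg$m_required)
  else m_of_n_filter(votes, "lasso", 1L)
  for (m in names(marginal_sets))
    say("[consensus] %s: %d genes in >= %d datasets", m,
        length(marginal_sets[[m]]), cfg$m_required)
  say("[consensus] lasso (%s): %d genes", cfg$joint_mode, length(joint_pool))

  pools <- combine_pools(marginal_sets, joint_pool)
  say("[consensus] marginal pool %d, joint pool %d, combined %d, common markers %d",
      pools$sizes["marginal_pool"], pools$sizes["joint_pool"],
      pools$sizes["all_selected"], pools$sizes["common_markers"])

  report <- if (length(pools$common_markers))
    marker_report(pools$common_markers, stats_list,
                  selections = c(marg_sel, joint_sel))
  else list(per_gene_stats = NULL, fc_ranges = NULL)

  res <- structure(
    c(pools[c("marginal_sets", "marginal_pool", "joint_pool",
              "common_markers", "all_selected", "sizes")],
      list(votes = votes, per_gene_stats = report$per_gene_stats,
           fc_ranges = report$fc_ranges, stats = stats_list,
           selections = c(marg_sel, joint_sel),
           common_genes = harm$common_genes, config = cfg)),
    class = "consensus_result")
  if (!is.null(out_dir)) write_run_artifacts(res, datasets, out_dir)
  res
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result>\n")
  cat(sprintf("  common genes analysed: %d\n", length(x$common_genes)))
  for (m in names(x$marginal_sets))
    cat(sprintf("  %-14s %4d genes in >= %d datasets\n",
                m, length(x$marginal_sets[[m]]), x$config$m_required))
  cat(sprintf("  marginal pool: %d | joint pool: %d | combined: %d\n",
              x$sizes["marginal_pool"], x$sizes["joint_pool"],
              x$sizes["all_selected"]))
  cat(sprintf("  common markers (%d): %s\n", x$sizes["common_markers"],
              paste(x$common_markers, collapse = ", ")))
  invisible(x)
}

# Serialize run artifacts: per-dataset stats and selections as TSV, the
# consensus and manifest as JSON. Identical inputs + config => identical files.
write_run_artifacts <- function(res, datasets, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in res$stats)
    write_marginal_stats(st, file.path(out_dir,
      paste0("stats_", attr(st, "dataset_id"), ".tsv")))
  sel_df <- do.call(rbind, lapply(res$selections, function(s)
    data.frame(dataset_id = s$dataset_id, method = s$method,
               gene = if (length(s$genes)) sort(s$genes) else NA_character_,
               stringsAsFactors = FALSE)))
  utils::write.table(sel_df, file.path(out_dir, "selections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  consensus <- list(
    sizes = as.list(res$sizes),
    marginal_sets = res$marginal_sets,
    marginal_pool = res$marginal_pool,
    joint_pool = res$joint_pool,
    common_markers = res$common_markers)
  jsonlite::write_json(consensus, file.path(out_dir, "consensus.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(res$per_gene_stats))
    utils::write.table(res$per_gene_stats,
                       file.path(out_dir, "marker_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = res$config[setdiff(names(res$config), "lasso")],
    lasso = unclass(res$config$lasso),
    datasets = lapply(datasets, function(d) list(
      dataset_id = d$dataset_id, platform_id = d$platform_id,
      sample_type = d$sample_type,
      n_probes = nrow(d$values), n_samples = ncol(d$values),
      n_case = sum(d$labels == "case"),
      n_control = sum(d$labels == "control"),
      checksum = dataset_checksum(d))),
    n_common_genes = length(res$common_genes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# Content checksum of a dataset (md5 of its canonical TSV serialisation).
dataset_checksum <- function(ds) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_expression_table(ds, tmp)
  unname(tools::md5sum(tmp))
}
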