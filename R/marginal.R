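# Marginal (per-gene, per-dataset) analysis: fold change, two-sample t-test
# on log2 values, Benjamini-Hochberg adjustment, and the three selection
# rules (top-k by FC, top-k by t-test p, FDR threshold).

#' Per-gene fold change between cases and controls
#'
#' On log2 data the linear-scale fold change is
#' `fc_ratio = 2^(mean_case - mean_control)`; `fc_magnitude` folds it to
#' `max(fc_ratio, 1/fc_ratio)` so up- and down-regulation rank together.
#'
#' @param gm A [gene_matrix()] on the log2 scale.
#' @return Data frame with columns `gene`, `fc_ratio`, `fc_magnitude`,
#'   `direction` (`"up"` iff `fc_ratio >= 1`).
#' @export
fold_change <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$scale != "log2") stop("fold_change needs log2-scale data")
  case <- gm$labels == "case"
  if (!any(case) || all(case)) stop("need both classes")
  d <- rowMeans(gm$values[, case, drop = FALSE]) -
       rowMeans(gm$values[, !case, drop = FALSE])
  fc <- 2^d
  data.frame(gene = rownames(gm$values), fc_ratio = fc,
             fc_magnitude = pmax(fc, 1 / fc),
             direction = ifelse(fc >= 1, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene two-sample t-test
#'
#' Vectorised over genes. The default is Welch's unequal-variance t with
#' Welch-Satterthwaite degrees of freedom (robust to the very unbalanced
#' group sizes typical of these cohorts); `"student"` gives the pooled
#' variance form. The statistic is case minus control, so up-regulation is
#' positive. If both groups are degenerate (zero variance): p = 1 when the
#' means agree, p = 0 when they differ.
#'
#' @param gm A [gene_matrix()] on the log2 scale.
#' @param variant `"welch"` (default) or `"student"`.
#' @return Data frame with columns `gene`, `t_stat`, `df`, `p_value`
#'   (two-sided).
#' @export
gene_t_test <- function(gm, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$scale != "log2") stop("gene_t_test needs log2-scale data")
  case <- gm$labels == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  x1 <- gm$values[, case, drop = FALSE]
  x2 <- gm$values[, !case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  degen <- se2 == 0
  if (any(degen)) {   # zero variance in both groups
    t_stat[degen] <- ifelse(m1[degen] == m2[degen], 0,
                            sign(m1[degen] - m2[degen]) * Inf)
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    df[degen] <- NA_real_
  }
  data.frame(gene = rownames(gm$values), t_stat = t_stat, df = df,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{j: p_(j) >= p_(i)} p_(j) * m / j`,
#' capped at 1, with input order preserved (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' All marginal statistics for one cohort
#'
#' @param gm A [gene_matrix()] on the log2 scale.
#' @param t_variant Passed to [gene_t_test()].
#' @return A `marginal_stats` data frame (columns `gene`, `fc_ratio`,
#'   `fc_magnitude`, `direction`, `t_stat`, `p_value`, `q_value`) with
#'   attributes `dataset_id` and `sample_type`.
#' @export
marginal_stats <- function(gm, t_variant = "welch") {
  fc <- fold_change(gm)
  tt <- gene_t_test(gm, t_variant)
  out <- data.frame(fc, t_stat = tt$t_stat, p_value = tt$p_value,
                    q_value = bh_adjust(tt$p_value),
                    stringsAsFactors = FALSE)
  as_marginal_stats(out, gm$dataset_id, gm$sample_type)
}

#' Tag a statistics table as marginal stats for one cohort
#'
#' Used both by [marginal_stats()] and to wrap externally reported per-gene
#' statistics (e.g. a published FC/p/q table) for [marker_report()].
#'
#' @param df Data frame with at least columns `gene` and `fc_ratio`.
#' @param dataset_id,sample_type Cohort metadata.
#' @return `df` with class `marginal_stats` and metadata attributes.
#' @export
as_marginal_stats <- function(df, dataset_id, sample_type) {
  stopifnot(all(c("gene", "fc_ratio") %in% names(df)))
  structure(df, class = c("marginal_stats", "data.frame"),
            dataset_id = dataset_id,
            sample_type = match.arg(sample_type, SAMPLE_TYPES))
}

#' Select the top k genes by fold change or t-test p-value
#'
#' `key = "fc"` ranks `fc_magnitude` decreasing (or `fc_ratio` decreasing
#' when `fc_mode = "ratio"`, i.e. up-regulation only); `key = "t_p"` ranks
#' the t-test p-value increasing. Ties are broken by gene symbol so the
#' selection is canonical regardless of input order. Exactly
#' `min(k, #genes)` genes are returned.
#'
#' @param stats A `marginal_stats` table.
#' @param key `"fc"` or `"t_p"`.
#' @param k Number of genes to keep (default 100).
#' @param fc_mode `"magnitude"` (two-sided, default) or `"ratio"` (up only).
#' @return A [selection_set()] with method `fc_top_k` or `t_top_k`.
#' @export
select_top_k <- function(stats, key = c("fc", "t_p"), k = 100L,
                         fc_mode = c("magnitude", "ratio")) {
  key <- match.arg(key); fc_mode <- match.arg(fc_mode)
  stopifnot(inherits(stats, "marginal_stats"), k >= 1L)
  ord <- switch(key,
    fc  = order(-(if (fc_mode == "magnitude") stats$fc_magnitude
                  else stats$fc_ratio), stats$gene),
    t_p = order(stats$p_value, stats$gene))
  genes <- stats$gene[ord][seq_len(min(k, nrow(stats)))]
  selection_set(attr(stats, "dataset_id"),
                if (key == "fc") "fc_top_k" else "t_top_k",
                genes, params = list(k = k, fc_mode = fc_mode))
}

#' Select genes below an FDR threshold
#'
#' @param stats A `marginal_stats` table with `q_value`.
#' @param alpha FDR level; genes with `q_value <= alpha` are selected
#'   (default 0.001).
#' @return A [selection_set()] with method `fdr_threshold` (possibly empty).
#' @export
select_fdr <- function(stats, alpha = 0.001) {
  stopifnot(inherits(stats, "marginal_stats"), "q_value" %in% names(stats),
            alpha > 0, alpha <= 1)
  selection_set(attr(stats, "dataset_id"), "fdr_threshold",
                stats$gene[stats$q_value <= alpha],
                params = list(alpha = alpha))
}

#' Write a marginal statistics table as TSV
#' @param stats A `marginal_stats` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marginal_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
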