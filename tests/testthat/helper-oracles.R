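# Independent brute-force oracles. These implement the definitions directly
# and inefficiently, so they can never share a bug with the package code
# they check.

# Benjamini-Hochberg by definition: q_i = min over sorted ranks j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    rank_i <- sum(p < p[i]) + 1L   # smallest sorted rank of p_i among ties
    o <- order(p)
    sorted <- p[o]
    min(1, min(sorted[rank_i:m] * m / (rank_i:m)))
  }, 0)
}

# Hypergeometric upper tail P(overlap >= k) by enumerating every possible
# draw of n from a universe of N with the first K elements marked.
hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Vote counts by nested loops over methods, datasets and genes.
votes_brute <- function(selections) {
  out <- list()
  for (s in selections) {
    if (is.null(out[[s$method]])) out[[s$method]] <- list()
    for (g in s$genes)
      out[[s$method]][[g]] <- c(out[[s$method]][[g]], s$dataset_id)
  }
  lapply(out, function(m) vapply(m, function(d) length(unique(d)), 0L))
}

# Cross-set interaction summary by a double loop over edges.
cross_set_brute <- function(g, set_a, set_b) {
  within_a <- 0L; a_to_b <- 0L
  touched <- character(0)
  both <- union(set_a, set_b)
  for (i in seq_len(nrow(g))) {
    a <- g$gene_a[i]; b <- g$gene_b[i]
    if (a %in% set_a && b %in% set_a) within_a <- within_a + 1L
    else if ((a %in% set_a && b %in% set_b) || (b %in% set_a && a %in% set_b))
      a_to_b <- a_to_b + 1L
    if (a %in% both && b %in% both) touched <- c(touched, a, b)
  }
  list(within_a = within_a, a_to_b = a_to_b,
       isolated = sort(setdiff(set_a, touched)))
}

# Small gene-level matrix with optional planted case effects in rows 1..n_sig.
make_gm <- function(seed, n_genes = 205, n_sig = 0, effect = 2,
                    n_case = 100, n_control = 100, sd = 0.5,
                    dataset_id = "D1", sample_type = "pbmc",
                    permute_labels = FALSE) {
  set.seed(seed)
  n <- n_case + n_control
  vals <- matrix(rnorm(n_genes * n, 8, sd), n_genes, n,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("S%03d", seq_len(n))))
  labels <- rep(c("case", "control"), c(n_case, n_control))
  if (n_sig > 0)
    vals[seq_len(n_sig), labels == "case"] <-
      vals[seq_len(n_sig), labels == "case"] + effect
  if (permute_labels) labels <- sample(labels)
  gene_matrix(dataset_id, sample_type, vals, labels)
}

# Minimal marginal_stats table from named fold-change magnitudes / p-values.
make_stats <- function(dataset_id = "D1", sample_type = "pbmc",
                       fc_magnitude = NULL, p_value = NULL, q_value = NULL) {
  genes <- names(fc_magnitude %||% p_value %||% q_value)
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!is.null(fc_magnitude)) {
    df$fc_ratio <- unname(fc_magnitude)
    df$fc_magnitude <- unname(fc_magnitude)
  } else df$fc_ratio <- 1
  if (!is.null(p_value)) df$p_value <- unname(p_value)
  if (!is.null(q_value)) df$q_value <- unname(q_value)
  as_marginal_stats(df, dataset_id, sample_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata <- function(...) {
  path <- system.file("extdata", ..., package = "crossmarker")
  stopifnot(nzchar(path))
  path
}
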