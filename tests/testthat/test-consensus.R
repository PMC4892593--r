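sel <- function(ds, method, genes)
  selection_set(ds, method, genes)

test_that("vote counting is per method and per distinct dataset", {
  v <- count_votes(list(sel("d1", "fc_top_k", c("g1", "g2")),
                        sel("d2", "fc_top_k", "g1"),
                        sel("d3", "fc_top_k", "g1"),
                        sel("d1", "t_top_k", "g2")))
  expect_identical(unname(v$counts$fc_top_k["g1"]), 3L)
  expect_identical(unname(v$counts$fc_top_k["g2"]), 1L)
  expect_identical(unname(v$counts$t_top_k["g2"]), 1L)
  expect_false("g3" %in% names(v$counts$fc_top_k))  # absent => count 0
  expect_identical(v$n_datasets$fc_top_k, 3L)

  expect_error(count_votes(list(sel("d1", "fc_top_k", "g1"),
                                sel("d1", "fc_top_k", "g2"))),
               "duplicate selection")
})

test_that("vote counts match the nested-loop oracle on random collections", {
  set.seed(44)
  genes <- sprintf("g%02d", 1:30)
  methods <- c("fc_top_k", "t_top_k", "fdr_threshold", "lasso")
  for (rep in 1:30) {
    sels <- list()
    for (m in sample(methods, sample(2:4, 1)))
      for (d in paste0("d", seq_len(sample(2:5, 1))))
        sels <- c(sels, list(sel(d, m, sample(genes, sample(0:12, 1)))))
    v <- count_votes(sels)
    brute <- votes_brute(sels)
    for (m in names(brute)) {
      expect_setequal(names(v$counts[[m]]), names(brute[[m]]))
      expect_identical(v$counts[[m]][sort(names(brute[[m]]))],
                       brute[[m]][sort(names(brute[[m]]))])
    }
  }
})

test_that("m-of-n filtering keeps genes at or above the threshold", {
  v <- count_votes(list(sel("d1", "lasso", c("g1", "g2", "g3")),
                        sel("d2", "lasso", c("g1", "g2")),
                        sel("d3", "lasso", c("g1", "g2")),
                        sel("d4", "lasso", "g1")))
  expect_identical(m_of_n_filter(v, "lasso", 3), c("g1", "g2"))
  expect_identical(m_of_n_filter(v, "lasso", 1), c("g1", "g2", "g3"))
  expect_error(m_of_n_filter(v, "lasso", 5), "exceeds")
  expect_error(m_of_n_filter(v, "fc_top_k", 1), "no selections")
  # raising m never enlarges the output
  for (m in 1:4)
    expect_true(all(m_of_n_filter(v, "lasso", m) %in%
                      m_of_n_filter(v, "lasso", max(1, m - 1))))
})

test_that("pool combination obeys inclusion-exclusion at the reported scale", {
  # pools sized like a published study: 126 marginal, 56 joint, 10 shared
  common <- sprintf("C%02d", 1:10)
  marginal <- list(fc_top_k = c(sprintf("M%03d", 1:116), common))
  joint <- c(sprintf("J%03d", 1:46), common)
  res <- combine_pools(marginal, joint)
  expect_identical(unname(res$sizes),
                   c(126L, 56L, 10L, 172L)[match(names(res$sizes),
                     c("marginal_pool", "joint_pool", "common_markers",
                       "all_selected"))])
  expect_setequal(res$common_markers, common)

  small <- combine_pools(list(m = c("a", "b", "c")), c("b", "c", "d"))
  expect_setequal(small$common_markers, c("b", "c"))
  expect_identical(unname(small$sizes["all_selected"]), 4L)

  disjoint <- combine_pools(list(m = c("a", "b")), c("c"))
  expect_length(disjoint$common_markers, 0)
})

test_that("union identity holds on random pools", {
  set.seed(55)
  pool <- sprintf("g%03d", 1:200)
  for (rep in 1:50) {
    ms <- replicate(3, sample(pool, sample(0:80, 1)), simplify = FALSE)
    jp <- sample(pool, sample(0:80, 1))
    res <- combine_pools(ms, jp)
    expect_identical(length(res$all_selected),
                     length(res$marginal_pool) + length(res$joint_pool) -
                       length(res$common_markers))
  }
})

test_that("marker report reproduces reported fold-change ranges by sample type", {
  stats_list <- read_marker_stats(extdata("sle_marker_stats_published.tsv"))
  expect_length(stats_list, 4)
  markers <- stats_list[[1]]$gene
  ifn <- c("IFI6", "IFI27", "IFI44L")
  rep <- marker_report(markers, stats_list, range_genes = ifn)
  ranges <- rep$fc_ranges
  expect_equal(ranges$fc_min[ranges$sample_type == "monocyte"], 8.82)
  expect_equal(ranges$fc_max[ranges$sample_type == "monocyte"], 251.66)
  expect_equal(ranges$fc_min[ranges$sample_type == "pbmc"], 3.73)
  expect_equal(ranges$fc_max[ranges$sample_type == "pbmc"], 74.06)
  expect_equal(ranges$fc_min[ranges$sample_type == "whole_blood"], 1.19)
  expect_equal(ranges$fc_max[ranges$sample_type == "whole_blood"], 1.87)
  expect_identical(nrow(rep$per_gene_stats), 40L)

  single <- marker_report("GSTO1", stats_list["GSE46907"])
  expect_equal(single$fc_ranges$fc_min, single$fc_ranges$fc_max)

  expect_error(marker_report(c("IFI6", "NOT_THERE"), stats_list),
               "missing from")
})

test_that("marker report flags which method selected a gene where", {
  st <- make_stats("d1", "pbmc", fc_magnitude = c(A = 5, B = 1.2))
  rep <- marker_report(c("A", "B"), list(st),
                       selections = list(sel("d1", "lasso", "A")))
  expect_identical(rep$per_gene_stats$sel_lasso, c(TRUE, FALSE))
})

test_that("display formatting rounds FC to 2 decimals and p to 2 sig figs", {
  df <- data.frame(gene = "A", dataset_id = "d", sample_type = "pbmc",
                   fc_ratio = 3.14159, p_value = 0.000123456)
  out <- format_marker_table(df)
  expect_identical(out$fc_ratio, "3.14")
  expect_identical(out$p_value, "1.23e-04")
})
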