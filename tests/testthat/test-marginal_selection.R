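gm_from <- function(case_rows, control_rows, genes = NULL) {
  vals <- cbind(case_rows, control_rows)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(vals)))
  dimnames(vals) <- list(genes, sprintf("s%02d", seq_len(ncol(vals))))
  gene_matrix("D1", "pbmc", vals,
              rep(c("case", "control"), c(ncol(case_rows), ncol(control_rows))))
}

test_that("fold change is 2^(difference of log2 group means)", {
  gm <- gm_from(matrix(c(3, 3,  1, 1,  1, 1), 3, 2, byrow = TRUE),
                matrix(c(1, 1,  1, 1,  2, 2), 3, 2, byrow = TRUE))
  fc <- fold_change(gm)
  expect_equal(fc$fc_ratio, c(4, 1, 0.5))
  expect_equal(fc$fc_magnitude, c(4, 1, 2))
  expect_identical(fc$direction, c("up", "up", "down"))
})

test_that("fold change is shift-invariant; t-test is affine-invariant", {
  set.seed(21)
  gm <- gm_from(matrix(rnorm(40), 10, 4), matrix(rnorm(60), 10, 6))
  shifted <- gm; shifted$values <- gm$values + 3.7
  expect_equal(fold_change(shifted)$fc_ratio, fold_change(gm)$fc_ratio)
  tt <- gene_t_test(gm)
  scaled <- gm; scaled$values <- gm$values * 2.5 + 1.1
  expect_equal(gene_t_test(scaled)$p_value, tt$p_value)
  expect_equal(gene_t_test(scaled)$t_stat, tt$t_stat)
})

test_that("Welch t matches its closed form and the stats oracle", {
  gm <- gm_from(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  tt <- gene_t_test(gm)
  # frozen from the Welch formulas: t = -3/sqrt(2/3), df = 4
  expect_equal(tt$t_stat, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.0213116411, tolerance = 1e-7)

  set.seed(31)
  gm2 <- gm_from(matrix(rnorm(5 * 20, sd = 0.7), 20), matrix(rnorm(9 * 20), 20))
  welch <- gene_t_test(gm2)
  student <- gene_t_test(gm2, "student")
  for (i in seq_len(20)) {
    x <- gm2$values[i, gm2$labels == "case"]
    y <- gm2$values[i, gm2$labels == "control"]
    ow <- stats::t.test(x, y)
    expect_equal(welch$t_stat[i], unname(ow$statistic))
    expect_equal(welch$df[i], unname(ow$parameter))
    expect_equal(welch$p_value[i], ow$p.value)
    os <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(student$t_stat[i], unname(os$statistic))
    expect_equal(student$p_value[i], os$p.value)
  }
})

test_that("degenerate zero-variance genes follow the stated conventions", {
  gm <- gm_from(matrix(c(1, 1,  1, 1,  2, 2), 3, 2, byrow = TRUE),
                matrix(c(1, 1,  1, 1,  1, 1), 3, 2, byrow = TRUE))
  gm$values[2, ] <- c(1, 1, 1, 1)  # identical everywhere
  tt <- gene_t_test(gm)
  expect_equal(tt$p_value, c(1, 1, 0))
  expect_equal(tt$t_stat[1:2], c(0, 0))

  one_per_group <- gene_matrix("D", "pbmc",
                               matrix(1:2, 1, 2, dimnames = list("G", c("a", "b"))),
                               c("case", "control"))
  expect_error(gene_t_test(one_per_group), ">= 2 samples")
})

test_that("BH adjustment matches the definitional oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (rep in 1:200) {
    p <- stats::runif(sample(1:200, 1))
    if (rep %% 3 == 0) p[sample(length(p), 1)] <- p[1]  # inject ties
    expect_lt(max(abs(bh_adjust(p) - bh_brute(p))), 1e-12)
  }
})

test_that("q-values order genes the same way as p-values", {
  set.seed(13)
  p <- stats::runif(500)^2
  q <- bh_adjust(p)
  expect_identical(order(p), order(q, p))
})

test_that("top-k selection ranks, tie-breaks and is order-canonical", {
  st <- make_stats(fc_magnitude = c(A = 3, B = 2, C = 10, D = 1, E = 5))
  expect_setequal(select_top_k(st, "fc", 3)$genes, c("C", "E", "A"))
  expect_length(select_top_k(st, "fc", 10)$genes, 5)

  tie <- make_stats(fc_magnitude = c(A = 2, B = 2, C = 3))
  expect_setequal(select_top_k(tie, "fc", 2)$genes, c("C", "A"))

  stp <- make_stats(p_value = c(A = 0.5, B = 0.001, C = 0.01, D = 0.2),
                    fc_magnitude = c(A = 1, B = 1, C = 1, D = 1))
  expect_setequal(select_top_k(stp, "t_p", 2)$genes, c("B", "C"))

  shuf <- st[sample(nrow(st)), ]
  attributes(shuf)[c("dataset_id", "sample_type")] <-
    attributes(st)[c("dataset_id", "sample_type")]
  class(shuf) <- class(st)
  expect_setequal(select_top_k(shuf, "fc", 3)$genes,
                  select_top_k(st, "fc", 3)$genes)
})

test_that("ratio mode ranks up-regulation only", {
  df <- data.frame(gene = c("UP", "DOWN", "FLAT"),
                   fc_ratio = c(4, 0.1, 1.2))
  df$fc_magnitude <- pmax(df$fc_ratio, 1 / df$fc_ratio)
  st <- as_marginal_stats(df, "D1", "pbmc")
  expect_setequal(select_top_k(st, "fc", 2, fc_mode = "magnitude")$genes,
                  c("DOWN", "UP"))
  expect_setequal(select_top_k(st, "fc", 2, fc_mode = "ratio")$genes,
                  c("UP", "FLAT"))
})

test_that("FDR selection applies <= at the stated level", {
  st <- make_stats(q_value = c(A = 0.0005, B = 0.001, C = 0.002))
  expect_setequal(select_fdr(st, 0.001)$genes, c("A", "B"))
  expect_length(select_fdr(st, 1e-5)$genes, 0)
  expect_length(select_fdr(st, 1)$genes, 3)
})
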