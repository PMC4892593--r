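test_that("generation is fully reproducible from the config seed", {
  cfg <- default_study_config(n_genes = 120, n_planted = 4, seed = 7)
  a <- generate_multidataset(cfg)
  b <- generate_multidataset(cfg)
  for (i in seq_along(a$datasets))
    expect_identical(a$datasets[[i]]$values, b$datasets[[i]]$values)
  expect_identical(a$probe_maps, b$probe_maps)
  expect_identical(a$truth, b$truth)
})

test_that("the default study design matches the four-cohort blood study", {
  cfg <- default_study_config()
  sizes <- t(vapply(cfg$cohorts, function(co) c(co$n_case, co$n_control),
                    integer(2)))
  expect_equal(unname(sizes),
               matrix(c(5L, 5L, 61L, 20L, 99L, 30L, 157L, 20L),
                      4, byrow = TRUE))
  expect_identical(vapply(cfg$cohorts, `[[`, "", "sample_type"),
                   c("monocyte", "pbmc", "whole_blood", "whole_blood"))
  expect_identical(default_study_config(), default_study_config())
  expect_equal(unname(cfg$attenuation[c("monocyte", "pbmc", "whole_blood")]),
               c(1, 0.6, 0.15))
})

test_that("platform panels intersect to exactly the configured shared core", {
  cfg <- default_study_config(n_genes = 150, seed = 3)
  sim <- generate_multidataset(cfg)
  panels <- lapply(sim$probe_maps, function(m) unique(unname(m$map)))
  expect_setequal(Reduce(intersect, panels), sim$truth$core_genes)
  # and each platform carries private genes beyond the core
  for (p in panels) expect_gt(length(setdiff(p, sim$truth$core_genes)), 0)
})

test_that("a planted gene outside the shared core is rejected", {
  cfg <- default_study_config(n_genes = 50, seed = 1)
  cfg$planted_markers <- data.frame(gene = "NOT_A_GENE", base_log2_effect = 2)
  expect_error(generate_multidataset(cfg), "absent from the shared core")
})

test_that("planted fold change realises its expectation over replicates", {
  # base log2 effect 3 at attenuation 1 => expected linear FC 2^3 = 8;
  # Monte-Carlo mean over 50 replicate cohorts at n = 100/100 sits in a
  # narrow band around it (pre-computed by simulation)
  fcs <- vapply(1:50, function(r) {
    cfg <- sim_config(list(cohort_spec("D", "P", "monocyte", 100, 100)),
                      n_genes = 50,
                      planted_markers = data.frame(gene = "G00007",
                                                   base_log2_effect = 3),
                      seed = 5000 + r)
    sim <- generate_multidataset(cfg)
    gm <- ensure_log_scale(collapse_probes(sim$datasets[[1]], sim$probe_maps[[1]]))
    fc <- fold_change(gm)
    fc$fc_ratio[fc$gene == "G00007"]
  }, 0)
  expect_gt(mean(fcs), 7)
  expect_lt(mean(fcs), 9)
})

test_that("null configuration gives calibrated type-I error", {
  cfg <- sim_config(list(cohort_spec("D", "P", "pbmc", 50, 50)),
                    n_genes = 1000, probes_per_gene = c(1L, 1L), seed = 99)
  sim <- generate_multidataset(cfg)
  gm <- ensure_log_scale(collapse_probes(sim$datasets[[1]], sim$probe_maps[[1]]))
  gm$values <- gm$values[sim$truth$core_genes, ]  # exclude private genes
  p <- gene_t_test(gm)$p_value
  band <- stats::qbinom(c(0.005, 0.995), length(p), 0.05) / length(p)
  expect_gte(mean(p < 0.05), band[1])
  expect_lte(mean(p < 0.05), band[2])
})

test_that("planted effects attenuate monotonically across sample types", {
  # realized mean FC per planted gene, averaged over 10 seed replicates,
  # must order monocyte > pbmc > whole blood under decreasing attenuation
  fc_by_type <- function(seed) {
    cfg <- default_study_config(n_genes = 200, n_planted = 5, seed = seed)
    sim <- generate_multidataset(cfg)
    sapply(sim$datasets, function(ds) {
      gm <- ensure_log_scale(collapse_probes(ds, sim$probe_maps[[ds$platform_id]]))
      fc <- fold_change(gm)
      stats::setNames(fc$fc_ratio, fc$gene)[sim$truth$planted$gene]
    })
  }
  reps <- lapply(1:10, fc_by_type)
  mean_fc <- Reduce(`+`, reps) / length(reps)   # genes x cohorts
  for (g in seq_len(nrow(mean_fc))) {
    expect_gt(mean_fc[g, 1], mean_fc[g, 2])                  # monocyte > pbmc
    expect_gt(mean_fc[g, 2], max(mean_fc[g, 3], mean_fc[g, 4]))  # pbmc > wb
  }
})

test_that("control-group means converge to the configured baselines", {
  cfg <- sim_config(list(cohort_spec("D", "P", "pbmc", 2, 400)),
                    n_genes = 300, probes_per_gene = c(1L, 1L),
                    probe_offset_sd = 0, probe_noise_sd = 1e-3,
                    frac_unannotated = 0, seed = 17)
  sim <- generate_multidataset(cfg)
  gm <- collapse_probes(sim$datasets[[1]], sim$probe_maps[[1]], "mean_of_probes")
  ctrl_mean <- rowMeans(gm$values[, sim$datasets[[1]]$labels == "control"])
  se <- cfg$noise_sd / sqrt(400)
  dev <- abs(ctrl_mean[sim$truth$core_genes] -
               sim$truth$core_baseline[sim$truth$core_genes])
  expect_lt(max(dev), 5 * se)
})
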