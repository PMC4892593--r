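# Synthetic multi-cohort generator. Emulates the situation of several
# case-control expression cohorts profiled on partially overlapping platform
# panels, with multi-probe genes and planted up-regulated markers whose
# effect attenuates by sample type (strongest in sorted monocytes, weakest
# in whole blood, where the signal is diluted across cell types).

#' Describe one synthetic cohort
#'
#' @param dataset_id,platform_id,sample_type Cohort metadata; cohorts sharing
#'   a `platform_id` share a probe panel and annotation.
#' @param n_case,n_control Group sizes (each >= 1).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(dataset_id, platform_id, sample_type, n_case, n_control) {
  sample_type <- match.arg(sample_type, SAMPLE_TYPES)
  stopifnot(n_case >= 1L, n_control >= 1L)
  structure(list(dataset_id = dataset_id, platform_id = platform_id,
                 sample_type = sample_type, n_case = as.integer(n_case),
                 n_control = as.integer(n_control)),
            class = "cohort_spec")
}

#' Configure the synthetic multi-cohort generator
#'
#' The generative model, per cohort: a control sample's log2 expression of
#' gene g is Normal(baseline_g, `noise_sd`); cases add
#' `attenuation[sample_type] * base_log2_effect` for each planted marker.
#' Every gene expands to 1..`probes_per_gene[2]` probes; a probe's value is
#' the gene value plus a per-probe constant offset (Normal(0,
#' `probe_offset_sd`)) plus independent measurement noise (Normal(0,
#' `probe_noise_sd`)), so multi-probe genes have distinct but correlated rows.
#' Platform panels consist of the shared core plus platform-private genes, so
#' the intersection of all panels is exactly the core.
#'
#' @param cohorts List of [cohort_spec()]s.
#' @param n_genes Number of core (shared) genes.
#' @param panel_overlap Fraction of a platform's panel made up by the shared
#'   core; the remaining `round(n_genes * (1 - panel_overlap))` genes are
#'   platform-private.
#' @param probes_per_gene Integer range `c(lo, hi)` of probes per gene.
#' @param planted_markers Data frame with columns `gene`, `base_log2_effect`
#'   (genes must belong to the shared core), or NULL for a null configuration.
#' @param attenuation Named multipliers on the planted log2 effect per sample
#'   type; must be > 0.
#' @param noise_sd Within-group SD of log2 expression around the gene baseline.
#' @param probe_offset_sd,probe_noise_sd Probe-level offset and noise SDs.
#' @param baseline_log2_range Range from which per-gene baselines are drawn.
#' @param frac_unannotated Fraction of extra probes carrying no gene
#'   annotation (exercises probe-collapse dropping).
#' @param seed Integer seed; the full output is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cohorts,
                       n_genes = 2000L,
                       panel_overlap = 0.8,
                       probes_per_gene = c(1L, 3L),
                       planted_markers = NULL,
                       attenuation = c(monocyte = 1, pbmc = 0.6,
                                       whole_blood = 0.15, other = 1),
                       noise_sd = 0.5,
                       probe_offset_sd = 0.2,
                       probe_noise_sd = 0.25,
                       baseline_log2_range = c(6, 12),
                       frac_unannotated = 0.02,
                       seed = 101L) {
  stopifnot(length(cohorts) >= 1L,
            all(vapply(cohorts, inherits, TRUE, "cohort_spec")),
            n_genes >= 1L, panel_overlap > 0, panel_overlap <= 1,
            length(probes_per_gene) == 2L,
            probes_per_gene[1] >= 1L, probes_per_gene[2] >= probes_per_gene[1],
            all(attenuation > 0), noise_sd > 0,
            baseline_log2_range[2] >= baseline_log2_range[1])
  if (!is.null(planted_markers)) {
    stopifnot(is.data.frame(planted_markers),
              all(c("gene", "base_log2_effect") %in% names(planted_markers)))
    planted_markers$gene <- toupper(planted_markers$gene)
  }
  structure(list(cohorts = cohorts, n_genes = as.integer(n_genes),
                 panel_overlap = panel_overlap,
                 probes_per_gene = as.integer(probes_per_gene),
                 planted_markers = planted_markers, attenuation = attenuation,
                 noise_sd = noise_sd, probe_offset_sd = probe_offset_sd,
                 probe_noise_sd = probe_noise_sd,
                 baseline_log2_range = baseline_log2_range,
                 frac_unannotated = frac_unannotated,
                 seed = as.integer(seed)),
            class = "sim_config")
}

core_gene_symbols <- function(n) sprintf("G%05d", seq_len(n))

#' Default four-cohort blood study design
#'
#' Reproduces the design of a four-cohort SLE case-control study: one small
#' monocyte cohort (5 cases / 5 controls), one PBMC cohort (61/20) and two
#' whole-blood cohorts (99/30 and 157/20), on three platforms (the two
#' whole-blood-adjacent cohorts share one). Planted-marker effects attenuate
#' monocyte 1.0 -> PBMC 0.6 -> whole blood 0.15, mirroring the dilution of a
#' monocyte-expressed interferon signature across sample types.
#'
#' @param n_genes Shared-core size (default 2000).
#' @param n_planted Number of planted up-regulated markers (default 0: a null
#'   configuration). Planted genes are taken at evenly spaced core indices
#'   with base log2 effects spread over `planted_effect_range`.
#' @param planted_effect_range Range of base log2 effects (default 1.5-3).
#' @param seed Seed (fixed default so two calls give equal configs).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
default_study_config <- function(n_genes = 2000L, n_planted = 0L,
                                 planted_effect_range = c(1.5, 3),
                                 seed = 101L, ...) {
  cohorts <- list(
    cohort_spec("DS1_MONO", "PLATA", "monocyte",      5L,  5L),
    cohort_spec("DS2_PBMC", "PLATB", "pbmc",         61L, 20L),
    cohort_spec("DS3_WB",   "PLATB", "whole_blood",  99L, 30L),
    cohort_spec("DS4_WB",   "PLATC", "whole_blood", 157L, 20L))
  planted <- NULL
  if (n_planted > 0L) {
    idx <- round(seq(1L, n_genes, length.out = n_planted))
    planted <- data.frame(
      gene = core_gene_symbols(n_genes)[idx],
      base_log2_effect = seq(planted_effect_range[1], planted_effect_range[2],
                             length.out = n_planted))
  }
  sim_config(cohorts, n_genes = n_genes, planted_markers = planted,
             seed = seed, ...)
}

# Deterministic sub-seed for stream k of a run; keeps values in 32-bit range
# so adding a cohort or platform never perturbs earlier streams.
fork_seed <- function(seed, k)
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)

#' Generate a synthetic multi-cohort study
#'
#' Draws probe-level expression for every cohort in `config` under the model
#' described in [sim_config()], together with per-platform probe annotations
#' and the ground truth of planted effects. Fully reproducible from
#' `config$seed`; data for cohort i depend only on the seed and i, so adding
#' a cohort never changes earlier cohorts' matrices.
#'
#' @param config A [sim_config()].
#' @return List with elements `datasets` (list of [expr_dataset()]),
#'   `probe_maps` (list of [probe_map()] keyed by platform id) and `truth`
#'   (list: `planted` data frame, `per_cohort` data frame of expected log2
#'   effects, `core_genes`, `core_baseline`).
#' @export
generate_multidataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  core <- core_gene_symbols(config$n_genes)
  planted <- config$planted_markers
  if (!is.null(planted) && !all(planted$gene %in% core))
    stop("planted gene(s) absent from the shared core: ",
         paste(setdiff(planted$gene, core), collapse = ", "))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # Global per-core-gene baselines (shared across platforms and cohorts).
  set.seed(fork_seed(config$seed, 0L))
  base_lo <- config$baseline_log2_range[1]
  base_hi <- config$baseline_log2_range[2]
  core_baseline <- stats::setNames(stats::runif(length(core), base_lo, base_hi), core)

  platforms <- unique(vapply(config$cohorts, `[[`, "", "platform_id"))
  n_private <- round(config$n_genes * (1 - config$panel_overlap))
  plat <- list()
  for (j in seq_along(platforms)) {
    pid <- platforms[j]
    set.seed(fork_seed(config$seed, 100L + j))
    private <- if (n_private > 0)
      sprintf("PRIV%s%05d", toupper(pid), seq_len(n_private)) else character(0)
    panel <- c(core, private)
    baseline <- c(core_baseline,
                  stats::setNames(stats::runif(length(private), base_lo, base_hi),
                                  private))
    n_probes <- sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
                       length(panel), replace = TRUE)
    probe_gene <- rep(panel, n_probes)
    probe_ids <- sprintf("%s_%06d", pid, seq_along(probe_gene))
    n_extra <- round(config$frac_unannotated * length(probe_ids))
    extra_ids <- if (n_extra > 0)
      sprintf("%s_X%05d", pid, seq_len(n_extra)) else character(0)
    plat[[pid]] <- list(
      panel = panel, baseline = baseline,
      probe_ids = c(probe_ids, extra_ids),
      probe_gene = c(probe_gene, rep(NA_character_, n_extra)),
      probe_offset = stats::rnorm(length(probe_ids) + n_extra,
                                  0, config$probe_offset_sd),
      map = probe_map(pid, stats::setNames(probe_gene, probe_ids)))
  }

  datasets <- vector("list", length(config$cohorts))
  truth_rows <- list()
  for (i in seq_along(config$cohorts)) {
    sp <- config$cohorts[[i]]
    pl <- plat[[sp$platform_id]]
    set.seed(fork_seed(config$seed, 1000L + i))
    n <- sp$n_case + sp$n_control
    labels <- c(rep("case", sp$n_case), rep("control", sp$n_control))
    sample_ids <- sprintf("%s_%s%02d", sp$dataset_id,
                          ifelse(labels == "case", "CASE", "CTRL"),
                          c(seq_len(sp$n_case), seq_len(sp$n_control)))
    # gene-level log2 values
    gvals <- matrix(stats::rnorm(length(pl$panel) * n, 0, config$noise_sd),
                    length(pl$panel), n,
                    dimnames = list(pl$panel, sample_ids))
    gvals <- gvals + pl$baseline[pl$panel]
    att <- config$attenuation[[sp$sample_type]]
    if (!is.null(planted) && nrow(planted)) {
      eff <- att * planted$base_log2_effect
      gvals[planted$gene, labels == "case"] <-
        gvals[planted$gene, labels == "case"] + eff
      truth_rows[[i]] <- data.frame(dataset_id = sp$dataset_id,
                                    gene = planted$gene,
                                    expected_log2_effect = eff)
    }
    # probe expansion: gene value + per-probe constant offset + iid noise
    annotated <- !is.na(pl$probe_gene)
    pvals <- matrix(stats::rnorm(length(pl$probe_ids) * n, 0, config$probe_noise_sd),
                    length(pl$probe_ids), n,
                    dimnames = list(pl$probe_ids, sample_ids))
    pvals[annotated, ] <- pvals[annotated, ] + gvals[pl$probe_gene[annotated], ]
    if (any(!annotated))
      pvals[!annotated, ] <- pvals[!annotated, ] +
        stats::runif(sum(!annotated), base_lo, base_hi)
    pvals <- pvals + pl$probe_offset
    datasets[[i]] <- expr_dataset(sp$dataset_id, sp$platform_id,
                                  sp$sample_type, pvals, labels)
  }

  truth <- list(
    planted = if (is.null(planted))
      data.frame(gene = character(0), base_log2_effect = numeric(0)) else planted,
    per_cohort = if (length(truth_rows)) do.call(rbind, truth_rows)
      else data.frame(dataset_id = character(0), gene = character(0),
                      expected_log2_effect = numeric(0)),
    core_genes = core,
    core_baseline = core_baseline)
  list(datasets = datasets,
       probe_maps = lapply(plat, `[[`, "map"),
       truth = truth)
}
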