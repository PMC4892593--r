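#!/usr/bin/env Rscript

# Step 2 -- run the cross-dataset consensus pipeline on the simulated study.
#
# Reads the cohorts back from disk exactly as external (GEO-style) matrices
# would be read, then: probe collapse -> common-gene restriction -> marginal
# selection (top-100 FC, top-100 t-test p, FDR <= 0.001) -> per-cohort lasso
# -> 3-of-4 voting -> marginal-pool x joint-pool intersection. Compares the
# recovered common markers against the generator's planted truth.

library(crossmarker)

in_dir <- "results/sim"
out_dir <- "results/run"
stopifnot(dir.exists(in_dir))

meta <- list(DS1_MONO = c("PLATA", "monocyte"),
             DS2_PBMC = c("PLATB", "pbmc"),
             DS3_WB   = c("PLATB", "whole_blood"),
             DS4_WB   = c("PLATC", "whole_blood"))
datasets <- lapply(names(meta), function(id)
  read_expression_table(file.path(in_dir, paste0(id, "_expr.tsv")),
                        id, meta[[id]][1], meta[[id]][2],
                        file.path(in_dir, paste0(id, "_labels.tsv"))))
platforms <- unique(vapply(meta, `[`, "", 1))
probe_maps <- lapply(platforms, function(p)
  read_probe_map(file.path(in_dir, paste0(p, "_probe_map.tsv")), p))
names(probe_maps) <- platforms

res <- run_pipeline(datasets, probe_maps, analysis_config(seed = 20101L),
                    out_dir = out_dir)
print(res)

truth <- jsonlite::read_json(file.path(in_dir, "truth.json"),
                             simplifyVector = TRUE)
planted <- truth$planted$gene
cat(sprintf("\nplanted recovery: %d / %d markers, %d false positive(s)\n",
            length(intersect(res$common_markers, planted)), length(planted),
            length(setdiff(res$common_markers, planted))))
cat(sprintf("missed: %s\n",
            paste(setdiff(planted, res$common_markers), collapse = ", ")))
cat(sprintf("artifacts in %s\n", out_dir))
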