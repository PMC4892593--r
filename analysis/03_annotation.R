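#!/usr/bin/env Rscript

# Step 3 -- offline annotation of the ten-gene SLE marker panel.
#
# Works on the shipped data: the published per-cohort statistics of the ten
# common SLE marker genes, a GO-biological-process gene-set fixture, and a
# local PPI edge list with GWAS-reported susceptibility genes. Reports the
# interferon-gene fold-change attenuation across sample types, gene-set
# over-representation, and which markers lack any interaction evidence.

library(crossmarker)

out_dir <- "results/annotation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
fixture <- function(f) system.file("extdata", f, package = "crossmarker")

stats_list <- read_marker_stats(fixture("sle_marker_stats_published.tsv"))
markers <- unique(stats_list[[1]]$gene)
ifn <- c("IFI6", "IFI27", "IFI44L")

rep <- marker_report(markers, stats_list, range_genes = ifn)
cat("interferon-gene FC ranges by sample type:\n")
print(rep$fc_ranges)
write.table(format_marker_table(rep$per_gene_stats),
            file.path(out_dir, "marker_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Over-representation against the shipped GO-BP sets. The shipped fixture has
# no full array panel, so the universe here is the union of all annotated
# genes -- an illustrative universe; on a real run use the commonly profiled
# genes from the harmonize step.
gsc <- read_gmt(fixture("go_bp_markers.gmt"))
gwas <- read.delim(fixture("sle_susceptibility_genes.tsv"))$gene
universe <- unique(c(markers, unlist(gsc$sets), gwas))
enr <- enrich(markers, universe, gsc)
cat("\ntop enriched biological processes (illustrative universe):\n")
print(enr[, c("term_id", "term_name", "k", "K", "p_value", "overlap_genes")])
write.table(enr, file.path(out_dir, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

g <- read_edge_list(fixture("sle_ppi_edges.tsv"))
ppi <- cross_set_interactions(g, markers, gwas)
cat(sprintf("\nPPI: %d marker-marker edges, %d marker-susceptibility edges\n",
            nrow(ppi$within_a), nrow(ppi$a_to_b)))
cat(sprintf("markers without any interaction evidence: %s\n",
            paste(ppi$isolated, collapse = ", ")))
jsonlite::write_json(
  list(within_markers = ppi$within_a, marker_to_susceptibility = ppi$a_to_b,
       isolated = ppi$isolated),
  file.path(out_dir, "ppi_report.json"), dataframe = "rows", digits = NA)
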