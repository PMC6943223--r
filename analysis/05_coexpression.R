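#!/usr/bin/env Rscript
# Stage 5: differential co-expression analysis of the DEGs.
#
# Builds one Pearson co-expression network per condition over the
# called DEGs (edge rule: |r| >= 0.9 and correlation-test p <= 0.05 on
# log2 normalized expression), computes per-gene degree and k-core in
# each network, and calls core regulatory factors by DifDegree >= 12
# and DifKcore >= 8. With only 3 replicates per condition the sample
# correlations are extremely noisy, so the per-gene metrics here are
# illustrative; analysis/06 quantifies hub recovery under a design
# with enough replicates.

suppressPackageStartupMessages(library(difnet))

cm <- read_count_matrix("results/data/counts.tsv",
                        "results/data/conditions.tsv")
degs <- read_deg_table("results/degs.tsv")
split <- split_by_direction(degs)
ids <- c(split$up, split$down)

nets <- coexpression_networks(cm, ids)
for (l in names(nets))
  write_coexpression_network(
    nets[[l]], sprintf("results/coexpression_%s.graphml", l),
    sprintf("results/coexpression_%s_edges.tsv", l))

report <- differential_report(nets$A, nets$B)
write.table(as.data.frame(report), "results/differential_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
s <- attr(report, "summary")
for (cond in names(s))
  cat(sprintf(
    "Network %s: %d nodes, %d connections (%d positive, %d negative)\n",
    cond, s[[cond]]$nodes, s[[cond]]$edges, s[[cond]]$positive_edges,
    s[[cond]]$negative_edges))
cat("Core regulatory factors (DifDegree >= 12 & DifKcore >= 8):",
    sum(report$is_core_regulator), "\n")
jsonlite::write_json(s, "results/coexpression_summary.json",
                     auto_unbox = TRUE, pretty = TRUE)
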