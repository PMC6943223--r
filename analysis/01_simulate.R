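#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Emulates a two-condition adenovirus-overexpression RNA-seq design:
# 2000 genes, 3 replicates per condition, 10% planted DEGs at
# |log2FC| = 2, two 15-gene co-expression modules (one active per
# condition), plus GO-like and pathway-like gene-set collections with
# 3 planted enriched sets each and typed gene/pathway relation tables.
# Writes all inputs plus the ground truth under results/data/.

suppressPackageStartupMessages(library(difnet))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

cfg <- simulation_config(n_genes = 2000, n_replicates = 3,
                         deg_fraction = 0.1, lfc_magnitude = 2,
                         n_modules = 2, module_size = 15, seed = seed)
gen <- generate_counts(cfg)
truth <- gen$truth

go <- generate_genesets(truth, n_sets = 50, n_enriched = 3,
                        kind = "go_like", seed = seed + 1)
pw <- generate_genesets(truth, n_sets = 50, n_enriched = 3,
                        kind = "pathway_like", seed = seed + 2)
grel <- generate_relations(truth$universe, 3000, seed = seed + 3)
prel <- generate_relations(names(pw$sets), 120, seed = seed + 4)
truth$enriched_set_ids <- pw$enriched_set_ids

write_count_matrix(gen$cm, file.path(out, "counts.tsv"),
                   file.path(out, "conditions.tsv"))
write_gmt(go, file.path(out, "go_like.gmt"))
write_gmt(pw, file.path(out, "pathway_like.gmt"))
write_relations(grel, file.path(out, "gene_relations.tsv"))
write_relations(prel, file.path(out, "pathway_relations.tsv"))
write_truth(truth, file.path(out, "truth.json"))

cat("Simulated", nrow(gen$cm$counts), "genes x",
    ncol(gen$cm$counts), "samples;",
    length(truth$deg_ids_up), "planted up,",
    length(truth$deg_ids_down), "planted down;",
    sum(!is.na(truth$module_membership)), "module genes in",
    cfg$n_modules, "modules.\n")
cat("Inputs written under", out, "\n")
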