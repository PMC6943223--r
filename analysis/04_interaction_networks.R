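#!/usr/bin/env Rscript
# Stage 4: typed interaction networks.
#
# Gene level: the induced subgraph of the KEGG-style gene relation
# table on the called DEGs. Pathway level: the subgraph of the pathway
# relation table on significantly enriched pathway sets (P <= 0.05).
# Nodes are ranked by degree centrality to nominate core genes and
# pathways. Writes GraphML + TSV exports under results/.

suppressPackageStartupMessages(library(difnet))

degs <- read_deg_table("results/degs.tsv")
split <- split_by_direction(degs)
grel <- read_relations("results/data/gene_relations.tsv")
sig_genes <- data.frame(
  id = c(split$up, split$down),
  direction = rep(c("up", "down"),
                  c(length(split$up), length(split$down))))
gnet <- build_interaction_network(sig_genes, grel, level = "gene")
write_interaction_network(gnet, "results/gene_network.graphml",
                          "results/gene_network_edges.tsv",
                          "results/gene_network_nodes.tsv")
cat("Gene network:", nrow(gnet$nodes), "nodes,", nrow(gnet$edges),
    "typed edges (", gnet$skipped_edges, "relations outside the DEG",
    "set skipped)\n")
top <- head(rank_by_degree(gnet), 5)
cat("Top degree genes:",
    paste(sprintf("%s(%d)", top$id, top$degree), collapse = " "),
    "\n")

prel <- read_relations("results/data/pathway_relations.tsv")
pe <- rbind(
  read.table("results/enrichment_pathway_like_up.tsv", header = TRUE,
             sep = "\t", stringsAsFactors = FALSE),
  read.table("results/enrichment_pathway_like_down.tsv",
             header = TRUE, sep = "\t", stringsAsFactors = FALSE))
pe <- pe[pe$significant & !duplicated(pe$set_id), , drop = FALSE]
if (nrow(pe)) {
  pnet <- build_interaction_network(
    data.frame(id = pe$set_id, direction = pe$direction,
               p_value = pe$p_value),
    prel, p_threshold = 0.05, level = "pathway")
  write_interaction_network(pnet, "results/pathway_network.graphml",
                            "results/pathway_network_edges.tsv",
                            "results/pathway_network_nodes.tsv")
  cat("Pathway network:", nrow(pnet$nodes), "nodes,",
      nrow(pnet$edges), "typed edges\n")
} else cat("No significant pathways; pathway network skipped\n")
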