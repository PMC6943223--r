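test_that("generation is deterministic given the config seed", {
  cfg <- simulation_config(n_genes = 100, seed = 42)
  g1 <- generate_counts(cfg)
  g2 <- generate_counts(cfg)
  expect_identical(g1$cm$counts, g2$cm$counts)
  expect_identical(g1$truth, g2$truth)
})

test_that("config validation rejects impossible designs", {
  expect_error(simulation_config(n_genes = -5), "n_genes")
  expect_error(simulation_config(deg_fraction = 1.5), "deg_fraction")
  expect_error(simulation_config(dispersion = -0.1), "dispersion")
  expect_error(simulation_config(n_genes = 10.5), "whole number")
  expect_error(simulation_config(n_genes = 50, deg_fraction = 0.9,
                                 n_modules = 2, module_size = 10),
               "exceed")
})

test_that("the planted DEG count follows the rounding rule", {
  gen <- generate_counts(simulation_config(n_genes = 2000,
                                           deg_fraction = 0.1,
                                           lfc_magnitude = 1,
                                           seed = 3))
  planted <- c(gen$truth$deg_ids_up, gen$truth$deg_ids_down)
  expect_length(planted, 200)
  expect_length(intersect(gen$truth$deg_ids_up,
                          gen$truth$deg_ids_down), 0)
  expect_equal(sum(gen$truth$true_lfc != 0), 200)
})

test_that("a null design has vanishing condition log-ratios", {
  cfg <- simulation_config(n_genes = 20, n_replicates = 300,
                           deg_fraction = 0, dispersion = 0,
                           baseline_mean_log_range = c(2, 2),
                           n_modules = 0, seed = 5)
  gen <- generate_counts(cfg)
  cm <- gen$cm
  in_a <- cm$condition == "A"
  ratio <- log2(rowMeans(cm$counts[, !in_a]) /
                rowMeans(cm$counts[, in_a]))
  expect_lt(max(abs(ratio)), 0.1)
})

test_that("counts follow the stated NB mean-variance relation", {
  # mu = 100, alpha = 0.2 -> variance 100 + 0.2 * 100^2 = 2100
  cfg <- simulation_config(n_genes = 5, n_replicates = 5000,
                           deg_fraction = 0, dispersion = 0.2,
                           baseline_mean_log_range = c(2, 2),
                           n_modules = 0, seed = 9)
  counts <- generate_counts(cfg)$cm$counts
  for (i in seq_len(nrow(counts))) {
    expect_lt(abs(mean(counts[i, ]) - 100) / 100, 0.05)
    expect_lt(abs(var(counts[i, ]) - 2100) / 2100, 0.10)
  }
})

test_that("planted DEG means are shifted by 2^lfc in condition B", {
  cfg <- simulation_config(n_genes = 50, n_replicates = 2000,
                           deg_fraction = 0.2, lfc_magnitude = 1.5,
                           dispersion = 0.05,
                           baseline_mean_log_range = c(2.5, 2.5),
                           n_modules = 0, seed = 11)
  gen <- generate_counts(cfg)
  cm <- gen$cm
  in_a <- cm$condition == "A"
  ratio <- log2(rowMeans(cm$counts[, !in_a]) /
                rowMeans(cm$counts[, in_a]))
  names(ratio) <- rownames(cm$counts)
  expect_equal(unname(ratio[gen$truth$deg_ids_up]),
               rep(1.5, length(gen$truth$deg_ids_up)),
               tolerance = 0.1)
  expect_equal(unname(ratio[gen$truth$deg_ids_down]),
               rep(-1.5, length(gen$truth$deg_ids_down)),
               tolerance = 0.1)
})

test_that("module genes co-vary in the active condition only", {
  cfg <- simulation_config(n_genes = 60, n_replicates = 30,
                           deg_fraction = 0, dispersion = 0.01,
                           baseline_mean_log_range = c(2, 3),
                           n_modules = 1, module_size = 8,
                           module_condition = "A", seed = 13)
  gen <- generate_counts(cfg)
  cm <- gen$cm
  mem <- gen$truth$module_membership
  expr <- log1p(cm$counts[, cm$condition == "A"])
  r <- cor(t(expr))
  in_mod <- !is.na(mem)
  module_pairs <- r[in_mod, in_mod][upper.tri(diag(sum(in_mod)))]
  other <- r[!in_mod, !in_mod][upper.tri(diag(sum(!in_mod)))]
  expect_gt(min(module_pairs), median(other))
  wt <- wilcox.test(module_pairs, other, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
  # modules are disjoint and each hub belongs to exactly one module
  expect_true(all(table(mem[!is.na(mem)]) == 8))
  hub_mod <- mem[gen$truth$hub_ids]
  expect_false(anyNA(hub_mod))
  expect_equal(length(unique(hub_mod)), length(gen$truth$hub_ids))
})

test_that("gene-set generation plants enrichment and round-trips GMT", {
  gen <- generate_counts(simulation_config(n_genes = 500,
                                           deg_fraction = 0.1,
                                           seed = 17))
  truth <- gen$truth
  degs <- c(truth$deg_ids_up, truth$deg_ids_down)
  coll <- generate_genesets(truth, n_sets = 40, n_enriched = 5,
                            seed = 21)
  expect_length(coll$sets, 40)
  expect_identical(coll$enriched_set_ids, names(coll$sets)[1:5])
  for (id in coll$enriched_set_ids) {
    frac <- length(intersect(coll$sets[[id]], degs)) /
      length(coll$sets[[id]])
    expect_gte(frac, 0.5)
  }
  # uniform (non-enriched) sets overlap DEGs at about deg_fraction
  unif <- setdiff(names(coll$sets), coll$enriched_set_ids)
  fr <- vapply(coll$sets[unif], function(s)
    length(intersect(s, degs)) / length(s), numeric(1))
  expect_lt(abs(mean(fr) - 0.1), 0.06)

  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(coll, f1)
  write_gmt(generate_genesets(truth, n_sets = 40, n_enriched = 5,
                              seed = 21), f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  back <- read_gmt(f1, universe = truth$universe)
  expect_identical(back$sets, coll$sets)

  expect_error(generate_genesets(truth, n_sets = 5,
                                 set_size_range = c(600, 700)),
               "universe")
  expect_error(generate_genesets(truth, n_sets = 2, n_enriched = 3),
               "n_enriched")
})

test_that("relation generation respects counts, types and weights", {
  ent <- sprintf("e%02d", 1:10)
  expect_equal(nrow(generate_relations(ent, 0)), 0)
  rel <- generate_relations(ent, 20, seed = 2)
  expect_equal(nrow(rel), 20)
  expect_equal(nrow(unique(rel[c("source", "target", "type")])), 20)
  expect_true(all(rel$source != rel$target))
  expect_true(all(rel$type %in% relation_types()))
  only_act <- generate_relations(ent, 15, type_weights = c(act = 1),
                                 seed = 3)
  expect_true(all(only_act$type == "act"))
  expect_true(all(only_act$directed))
  expect_error(generate_relations(ent, 5,
                                  type_weights = c(frobnicate = 1)),
               "unknown relation type")
  expect_error(generate_relations(ent, 1000), "ordered entity pairs")
  # bin/com are undirected, the rest directed
  rel2 <- generate_relations(sprintf("x%03d", 1:50), 300, seed = 4)
  expect_identical(rel2$directed,
                   !(rel2$type %in% c("bin", "com")))
})
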