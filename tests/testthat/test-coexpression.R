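test_that("pearson matches hand evaluation and rejects degenerates", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(1:2, 1:2), "length")
  expect_error(pearson(1:4, rep(2, 4)), "zero variance")
})

test_that("k-core peeling matches the brute-force oracle", {
  # triangle: every node in the 2-core
  tri <- fake_net("A", c("a", "b", "c"),
                  clique_edges(c("a", "b", "c")))
  expect_equal(unname(kcore_decomposition(tri)), rep(2L, 3))
  # star with 6 leaves: the 2-core is empty, all core numbers 1
  star <- fake_net("A", c("hub", paste0("l", 1:6)),
                   data.frame(gene1 = "hub",
                              gene2 = paste0("l", 1:6)))
  expect_equal(unname(kcore_decomposition(star)), rep(1L, 7))
  # isolated node
  iso <- fake_net("A", c("a", "b", "c"),
                  data.frame(gene1 = "a", gene2 = "b"))
  expect_equal(kcore_decomposition(iso)[["c"]], 0L)
  # 100 random graphs vs the repeated-deletion oracle and igraph
  i <- 0
  for (p in c(0.1, 0.3, 0.5)) {
    for (rep in 1:34) {
      i <- i + 1
      if (i > 100) break
      g <- rand_graph(n = sample(4:25, 1), p = p, seed = 1000 + i)
      net <- fake_net("A", g$nodes, g$edges)
      mine <- kcore_decomposition(net)
      expect_identical(mine, oracle_kcore(g$nodes, g$edges))
      ig <- igraph::graph_from_data_frame(
        g$edges, directed = FALSE,
        vertices = data.frame(name = g$nodes))
      expect_equal(mine[g$nodes],
                   igraph::coreness(ig)[g$nodes],
                   ignore_attr = TRUE)
    }
  }
})

test_that("condition networks apply the dual edge rule on shared nodes", {
  # two genes driven by one latent factor correlate positively
  cfg <- coexpression_study_config(seed = 73, n_genes = 30,
                                   module_size = 5)
  gen <- generate_counts(cfg)
  net_a <- build_condition_network(gen$cm, gen$truth$universe, "A")
  mod <- names(gen$truth$module_membership)[
    !is.na(gen$truth$module_membership)]
  pair_edges <- net_a$edges[net_a$edges$gene1 %in% mod &
                            net_a$edges$gene2 %in% mod, ]
  expect_gt(nrow(pair_edges), 0)
  expect_true(all(pair_edges$sign == "positive"))
  expect_true(all(abs(net_a$edges$r) >= 0.9))
  expect_identical(net_a$edges$sign == "positive",
                   net_a$edges$r > 0)
  # both condition networks share one node set
  net_b <- build_condition_network(gen$cm, gen$truth$universe, "B")
  expect_identical(net_a$nodes, net_b$nodes)
  expect_error(build_condition_network(gen$cm, c("nope"), "A"),
               "absent")
})

test_that("null edge density matches the correlation-test level", {
  # independent genes, n = 3: |r| >= 0.9 is implied by p <= 0.05
  # (the t cutoff at df = 1 corresponds to |r| ~ 0.997), so the
  # expected density is the test level itself
  cfg <- simulation_config(n_genes = 120, n_replicates = 3,
                           deg_fraction = 0, dispersion = 0,
                           baseline_mean_log_range = c(3, 3),
                           n_modules = 0, seed = 79)
  gen <- generate_counts(cfg)
  net <- build_condition_network(gen$cm, gen$truth$universe, "A")
  n_pairs <- choose(length(net$nodes), 2)
  dens <- nrow(net$edges) / n_pairs
  se <- sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(dens - 0.05), 4 * se)
})

test_that("fewer than 3 samples in a condition is an explicit error", {
  m <- matrix(rpois(40, 50), nrow = 10)
  cm <- make_cm(m, condition = c("A", "A", "B", "B"))
  expect_error(build_condition_network(cm, rownames(m)[1:5], "A"),
               "fewer than 3")
})

test_that("the differential report implements the Dif thresholds", {
  nodes <- c(sprintf("c%02d", 1:10), sprintf("x%02d", 1:5), "solo")
  # gene c01 sits in a 10-clique: degree 9, core 9 -> NOT called
  cl <- clique_edges(sprintf("c%02d", 1:10))
  net_a <- fake_net("A", nodes, cl)
  net_b <- fake_net("B", nodes)
  rep1 <- differential_report(net_a, net_b)
  g1 <- rep1[rep1$gene == "c01", ]
  expect_equal(g1$degree_A, 9)
  expect_equal(g1$kcore_A, 9)
  expect_false(g1$is_core_regulator)        # 9 < 12
  # add 5 pendant partners to c01: degree 14, core still 9 -> called
  ext <- rbind(cl, data.frame(gene1 = "c01",
                              gene2 = sprintf("x%02d", 1:5)))
  rep2 <- differential_report(fake_net("A", nodes, ext), net_b)
  g2 <- rep2[rep2$gene == "c01", ]
  expect_equal(g2$degree_A, 14)
  expect_equal(g2$kcore_A, 9)
  expect_equal(g2$dif_degree, 14)
  expect_equal(g2$dif_kcore, 9)
  expect_true(g2$is_core_regulator)
  # every other gene stays uncalled
  expect_equal(sum(rep2$is_core_regulator), 1)
  # kcore <= degree everywhere
  expect_true(all(rep2$kcore_A <= rep2$degree_A))
  expect_true(all(rep2$kcore_B <= rep2$degree_B))
})

test_that("identical networks give zero metrics and no calls", {
  g <- rand_graph(15, 0.3, seed = 83)
  net <- fake_net("A", g$nodes, g$edges)
  net2 <- fake_net("B", g$nodes, g$edges)
  rep0 <- differential_report(net, net2)
  expect_true(all(rep0$dif_degree == 0))
  expect_true(all(rep0$dif_kcore == 0))
  expect_false(any(rep0$is_core_regulator))
})

test_that("condition relabeling swaps columns but not Dif metrics", {
  gA <- rand_graph(15, 0.4, seed = 89)
  gB <- rand_graph(15, 0.15, seed = 97)
  net_a <- fake_net("A", gA$nodes, gA$edges)
  net_b <- fake_net("B", gA$nodes, gB$edges)
  r1 <- differential_report(net_a, net_b, dif_degree_min = 2,
                            dif_kcore_min = 1)
  r2 <- differential_report(net_b, net_a, dif_degree_min = 2,
                            dif_kcore_min = 1)
  expect_equal(r1$degree_A, r2$degree_B)
  expect_equal(r1$kcore_A, r2$kcore_B)
  expect_equal(r1$dif_degree, r2$dif_degree)
  expect_equal(r1$dif_kcore, r2$dif_kcore)
  expect_equal(r1$is_core_regulator, r2$is_core_regulator)
})

test_that("node-set mismatch fails listing the symmetric difference", {
  net_a <- fake_net("A", c("a", "b"))
  net_b <- fake_net("B", c("a", "zzz"))
  expect_error(differential_report(net_a, net_b), "zzz")
})

test_that("edge-sign totals always sum to the edge count", {
  for (seed in c(101, 103)) {
    gen <- generate_counts(coexpression_study_config(seed = seed,
                                                     n_genes = 60))
    nets <- coexpression_networks(gen$cm, gen$truth$universe)
    s <- network_summary(nets$A, nets$B)
    for (cond in names(s))
      expect_equal(s[[cond]]$positive_edges +
                     s[[cond]]$negative_edges, s[[cond]]$edges)
  }
})

test_that("a planted module densifies only its active condition", {
  wins <- 0
  for (seed in 1:10) {
    gen <- generate_counts(coexpression_study_config(
      seed = 110 + seed, n_genes = 60, module_size = 8))
    mod <- names(gen$truth$module_membership)[
      !is.na(gen$truth$module_membership)]
    nets <- coexpression_networks(gen$cm, gen$truth$universe)
    dens <- vapply(nets, function(n) {
      e <- n$edges
      sum(e$gene1 %in% mod & e$gene2 %in% mod) / choose(8, 2)
    }, numeric(1))
    wins <- wins + (dens["A"] > dens["B"])
  }
  expect_gte(wins, 9)
})
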