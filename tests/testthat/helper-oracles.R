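# Independent brute-force oracles used to check the package's
# implementations. Each is written directly from the defining formula,
# not from the implementation under test.

# BH step-up by its definition: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    suffix <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(suffix))
  }
  q
}

# hypergeometric upper tail P(X >= overlap) by direct summation of
# binomial coefficients
oracle_hyper_upper <- function(overlap, set_size, n_degs, universe) {
  ks <- overlap:min(set_size, n_degs)
  sum(choose(n_degs, ks) * choose(universe - n_degs, set_size - ks)) /
    choose(universe, set_size)
}

# exact conditional NB p-value by plain enumeration on the raw
# probability scale
oracle_nb_exact <- function(k_a, k_b, mu_a, mu_b, var_a, var_b) {
  pmf <- function(x, mu, v) {
    if (v > mu) dnbinom(x, mu = mu, size = mu^2 / (v - mu))
    else dpois(x, mu)
  }
  total <- k_a + k_b
  pr <- vapply(0:total, function(a)
    pmf(a, mu_a, var_a) * pmf(total - a, mu_b, var_b), numeric(1))
  p_obs <- pr[k_a + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]) / sum(pr))
}

# k-core by repeated deletion: for every k, prune nodes of degree < k
# until stable; a node's core number is the largest k it survives
oracle_kcore <- function(nodes, edges) {
  core <- setNames(integer(length(nodes)), nodes)
  for (k in seq_along(nodes)) {
    alive <- nodes
    repeat {
      deg <- setNames(integer(length(alive)), alive)
      keep <- edges[[1]] %in% alive & edges[[2]] %in% alive
      if (any(keep)) {
        tb <- table(c(edges[[1]][keep], edges[[2]][keep]))
        deg[names(tb)] <- as.integer(tb)
      }
      drop <- alive[deg < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
    }
    if (!length(alive)) break
    core[alive] <- k
  }
  core
}

# Erdos-Renyi style random undirected simple graph
rand_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(gene1 = pairs[keep, 1],
                          gene2 = pairs[keep, 2],
                          stringsAsFactors = FALSE))
}

# wrap a node/edge list as a coexpression_network-shaped object
fake_net <- function(condition, nodes, edges = NULL,
                     sign = "positive") {
  if (is.null(edges))
    edges <- data.frame(gene1 = character(0), gene2 = character(0))
  if (is.null(edges$r)) edges$r <- rep(0.95, nrow(edges))
  if (is.null(edges$sign)) edges$sign <- rep(sign, nrow(edges))
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 n_samples = NA, r_min = 0.9, alpha = 0.05,
                 excluded = character(0)),
            class = "coexpression_network")
}

clique_edges <- function(nodes) {
  pairs <- t(combn(nodes, 2))
  data.frame(gene1 = pairs[, 1], gene2 = pairs[, 2],
             stringsAsFactors = FALSE)
}

read_tsv_helper <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             stringsAsFactors = FALSE)
}

# small count matrix with explicit values
make_cm <- function(counts, condition = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.null(condition))
    condition <- rep(c("A", "B"), each = ncol(counts) / 2)
  count_matrix(counts, condition)
}
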