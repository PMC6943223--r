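#' Pearson product-moment correlation of two expression profiles
#'
#' Thin validated wrapper around [stats::cor()]: pairs with fewer than
#' 3 observations or zero variance have no defined correlation and are
#' rejected so callers can exclude (and log) them.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop2("x and y must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop2("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' Per-condition co-expression network over a gene list
#'
#' Computes Pearson correlations between all gene pairs on
#' `log2(normalized count + 1)` within one condition and keeps an edge
#' when `|r| >= r_min` and the two-sided correlation test
#' (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`) has `p <= alpha`. The node
#' set is fixed to the genes with non-zero expression variance in BOTH
#' conditions, so that the two condition networks are built on one
#' shared node set and stay comparable; zero-variance genes are
#' excluded and listed in the `excluded` attribute.
#'
#' @param cm a [count_matrix()].
#' @param genes gene ids to include (typically the called DEGs).
#' @param condition which condition's samples to use (a level of
#'   `cm$condition`).
#' @param r_min minimum absolute Pearson correlation (default 0.9; with
#'   few replicates the t-test alone is extremely permissive, so the
#'   hard threshold carries most of the filtering).
#' @param alpha correlation-test significance level (default 0.05).
#' @param sf size factors; estimated from `cm` when NULL.
#' @return A `coexpression_network`: list with `condition`, `nodes`
#'   (shared node set), `edges` (data.frame `gene1`, `gene2`, `r`,
#'   `sign`), `n_samples`, and attribute `excluded`.
#' @export
build_condition_network <- function(cm, genes, condition,
                                    r_min = 0.9, alpha = 0.05,
                                    sf = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  assert_scalar_number(r_min, "r_min", min = 0, max = 1)
  assert_scalar_number(alpha, "alpha", min = 0, max = 1)
  if (!condition %in% cm_condition_levels(cm))
    stop2("unknown condition: ", condition)
  missing <- setdiff(genes, rownames(cm$counts))
  if (length(missing))
    stop2("genes absent from the count matrix: ",
          paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  expr <- log2(sweep(cm$counts[genes, , drop = FALSE], 2, sf, "/") + 1)

  # shared node set: defined (non-zero) variance in both conditions
  lv <- cm_condition_levels(cm)
  var_ok <- rep(TRUE, length(genes))
  for (l in lv) {
    e <- expr[, cm$condition == l, drop = FALSE]
    if (ncol(e) < 3)
      stop2("condition ", l, " has fewer than 3 samples; ",
            "correlations are not estimable")
    var_ok <- var_ok & apply(e, 1, stats::var) > 0
  }
  nodes <- genes[var_ok]
  excluded <- genes[!var_ok]

  e <- expr[nodes, cm$condition == condition, drop = FALSE]
  n <- ncol(e)
  r <- stats::cor(t(e))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  keep <- abs(r) >= r_min & p <= alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene1 = nodes[idx[, 1]], gene2 = nodes[idx[, 2]],
                      r = r[idx],
                      sign = ifelse(r[idx] > 0, "positive",
                                    "negative"),
                      stringsAsFactors = FALSE)
  edges <- edges[order_c(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 n_samples = n, r_min = r_min, alpha = alpha,
                 excluded = excluded),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network [", x$condition, "]: ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "positive"), " positive, ",
      sum(x$edges$sign == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' Build both condition networks on one shared node set
#'
#' @inheritParams build_condition_network
#' @return Named list of two `coexpression_network`s (one per condition
#'   level).
#' @export
coexpression_networks <- function(cm, genes, r_min = 0.9,
                                  alpha = 0.05, sf = NULL) {
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  lv <- cm_condition_levels(cm)
  nets <- lapply(lv, function(l)
    build_condition_network(cm, genes, l, r_min = r_min,
                            alpha = alpha, sf = sf))
  names(nets) <- lv
  nets
}

node_degrees <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    tb <- table(c(net$edges$gene1, net$edges$gene2))
    d[names(tb)] <- as.integer(tb)
  }
  d
}

#' k-core decomposition by iterative peeling
#'
#' The core number of a node is the largest k such that the node
#' survives iterative removal of all nodes of degree < k. Implemented
#' by the standard peeling order: repeatedly remove a minimum-degree
#' node, assigning it the running maximum of the minimum degrees seen.
#'
#' @param net a `coexpression_network`, or any list with `nodes` (ids)
#'   and `edges` (data.frame whose first two columns are endpoint ids)
#'   describing an undirected simple graph.
#' @return Named integer vector of core numbers (isolated nodes have
#'   core 0).
#' @export
kcore_decomposition <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  core <- stats::setNames(integer(n), nodes)
  if (n == 0) return(core)
  e1 <- match(net$edges[[1]], nodes)
  e2 <- match(net$edges[[2]], nodes)
  deg <- tabulate(c(e1, e2), nbins = n)
  adj <- vector("list", n)
  for (j in seq_along(e1)) {
    adj[[e1[j]]] <- c(adj[[e1[j]]], e2[j])
    adj[[e2[j]]] <- c(adj[[e2[j]]], e1[j])
  }
  alive <- rep(TRUE, n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  core
}

#' Differential co-expression report and core-regulator calls
#'
#' Compares the two condition networks gene by gene: degree and core
#' number in each network, their absolute differences
#' (`dif_degree = |degree_A - degree_B|`,
#' `dif_kcore = |kcore_A - kcore_B|`), and the core-regulatory-factor
#' call `dif_degree >= dif_degree_min & dif_kcore >= dif_kcore_min`
#' (defaults 12 and 8). Both networks must share one node set.
#'
#' @param net_a,net_b the two condition `coexpression_network`s.
#' @param dif_degree_min,dif_kcore_min core-regulator thresholds.
#' @return Data.frame of class `differential_network_report` with
#'   columns `gene`, `degree_A`, `degree_B`, `kcore_A`, `kcore_B`,
#'   `dif_degree`, `dif_kcore`, `is_core_regulator`; attribute
#'   `summary` holds per-network totals (nodes, edges, positive and
#'   negative edge counts).
#' @export
differential_report <- function(net_a, net_b, dif_degree_min = 12,
                                dif_kcore_min = 8) {
  stopifnot(inherits(net_a, "coexpression_network"),
            inherits(net_b, "coexpression_network"))
  if (!setequal(net_a$nodes, net_b$nodes)) {
    dif <- c(setdiff(net_a$nodes, net_b$nodes),
             setdiff(net_b$nodes, net_a$nodes))
    stop2("condition networks have different node sets; ",
          "symmetric difference: ",
          paste(utils::head(dif, 10), collapse = ", "))
  }
  genes <- net_a$nodes
  deg_a <- node_degrees(net_a)[genes]
  deg_b <- node_degrees(net_b)[genes]
  core_a <- kcore_decomposition(net_a)[genes]
  core_b <- kcore_decomposition(net_b)[genes]
  stopifnot(all(core_a <= deg_a), all(core_b <= deg_b))
  out <- data.frame(gene = genes,
                    degree_A = as.integer(deg_a),
                    degree_B = as.integer(deg_b),
                    kcore_A = as.integer(core_a),
                    kcore_B = as.integer(core_b), row.names = NULL)
  out$dif_degree <- abs(out$degree_A - out$degree_B)
  out$dif_kcore <- abs(out$kcore_A - out$kcore_B)
  out$is_core_regulator <- out$dif_degree >= dif_degree_min &
    out$dif_kcore >= dif_kcore_min
  class(out) <- c("differential_network_report", "data.frame")
  attr(out, "summary") <- network_summary(net_a, net_b)
  attr(out, "thresholds") <- c(dif_degree_min = dif_degree_min,
                               dif_kcore_min = dif_kcore_min)
  out
}

#' Per-network node/edge totals
#'
#' @param ... `coexpression_network`s.
#' @return Named list (by condition) of lists with `nodes`, `edges`,
#'   `positive_edges`, `negative_edges`.
#' @export
network_summary <- function(...) {
  nets <- list(...)
  out <- lapply(nets, function(n) list(
    nodes = length(n$nodes),
    edges = nrow(n$edges),
    positive_edges = sum(n$edges$sign == "positive"),
    negative_edges = sum(n$edges$sign == "negative")))
  names(out) <- vapply(nets, `[[`, character(1), "condition")
  out
}

#' Export a co-expression network
#'
#' GraphML plus an edge-list TSV (`gene1`, `gene2`, `r`, `sign`).
#'
#' @param net a `coexpression_network`.
#' @param graphml_path,edges_path output paths (NULL to skip).
#' @export
write_coexpression_network <- function(net, graphml_path = NULL,
                                       edges_path = NULL) {
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) write_tsv(net$edges, edges_path)
  invisible(net)
}
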