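#' Build a typed interaction network over significant nodes
#'
#' Induces the subgraph of a typed relation table on a set of
#' significant entities (DEGs at gene level, enriched pathways at
#' pathway level). When `significant` carries a `p_value` column, only
#' entries with `p_value <= p_threshold` are retained as nodes.
#' Relations whose endpoints are not both retained are skipped (counted
#' in the `skipped_edges` attribute — annotation mismatch is expected,
#' not fatal); self-loops are dropped; for undirected types the
#' (u, v, type) and (v, u, type) forms deduplicate to one edge.
#' Isolated retained nodes stay in the network.
#'
#' @param significant data.frame with columns `id`, `direction`
#'   (`up`/`down`) and optionally `p_value`.
#' @param relations a [relation_table()].
#' @param p_threshold node-inclusion cutoff applied to `p_value` when
#'   present (default 0.05).
#' @param level `"gene"` or `"pathway"` (metadata only).
#' @return An `interaction_network`: list with `graph` (an undirected
#'   igraph with edge attributes `type`, `directed`, `src`, `tgt` and
#'   vertex attributes `regulation`, `degree`), `nodes` (data.frame
#'   `id`, `regulation`, `degree`), `edges` (data.frame `source`,
#'   `target`, `type`, `directed`), `isolated` (ids), `level`.
#' @export
build_interaction_network <- function(significant, relations,
                                      p_threshold = 0.05,
                                      level = c("gene", "pathway")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(significant),
            all(c("id", "direction") %in% names(significant)))
  if (anyNA(significant$direction))
    stop2("every significant id needs a direction")
  keep <- significant
  if ("p_value" %in% names(keep))
    keep <- keep[keep$p_value <= p_threshold, , drop = FALSE]
  ids <- unique(as.character(keep$id))

  rel <- as.data.frame(relations, stringsAsFactors = FALSE)
  n_input <- nrow(rel)
  rel <- rel[rel$source != rel$target, , drop = FALSE]
  inside <- rel$source %in% ids & rel$target %in% ids
  skipped <- sum(!inside)
  rel <- rel[inside, , drop = FALSE]
  if (skipped > 0)
    message("build_interaction_network: skipped ", skipped, " of ",
            n_input, " relations with endpoints outside the ",
            "significant ", level, " set")

  # canonical orientation for undirected types so reversed duplicates
  # collapse to one edge
  if (nrow(rel) > 0) {
    undir <- !rel$directed
    flip <- undir & gt_c(rel$source, rel$target)
    tmp <- rel$source[flip]
    rel$source[flip] <- rel$target[flip]
    rel$target[flip] <- tmp
    rel <- rel[!duplicated(rel[c("source", "target", "type")]), ,
               drop = FALSE]
    rel <- rel[order_c(rel$source, rel$target, rel$type), ,
               drop = FALSE]
  }

  reg <- keep$direction[match(ids, keep$id)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = rel$source, to = rel$target, type = rel$type,
               directed = rel$directed, src = rel$source,
               tgt = rel$target, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, regulation = reg,
                          stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  igraph::V(g)$degree <- deg
  nodes <- data.frame(id = ids, regulation = reg,
                      degree = as.integer(deg[ids]), row.names = NULL)
  structure(list(graph = g, nodes = nodes,
                 edges = data.frame(source = rel$source,
                                    target = rel$target,
                                    type = rel$type,
                                    directed = rel$directed,
                                    row.names = NULL),
                 isolated = nodes$id[nodes$degree == 0],
                 level = level, skipped_edges = skipped),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network (", x$level, "): ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " typed edges, ",
      length(x$isolated), " isolated\n", sep = "")
  invisible(x)
}

#' Rank network nodes by degree centrality
#'
#' Degree counts every incident typed edge (in + out for directed
#' types). High-degree nodes are the network's candidate core
#' pathways/genes.
#'
#' @param net an `interaction_network`.
#' @return Data.frame `id`, `degree` in descending degree order with
#'   lexicographic id tie-break.
#' @export
rank_by_degree <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  nodes <- net$nodes
  out <- nodes[order_c(-nodes$degree, nodes$id),
               c("id", "degree"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an interaction network
#'
#' Writes GraphML (attributes preserved for graph viewers), an
#' edge-list TSV (`source`, `target`, `type`) and a node-table TSV
#' (`id`, `regulation`, `degree`).
#'
#' @param net an `interaction_network`.
#' @param graphml_path,edges_path,nodes_path output paths (NULL to
#'   skip).
#' @export
write_interaction_network <- function(net, graphml_path = NULL,
                                      edges_path = NULL,
                                      nodes_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    write_tsv(net$edges[c("source", "target", "type")], edges_path)
  if (!is.null(nodes_path))
    write_tsv(net$nodes, nodes_path)
  invisible(net)
}
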