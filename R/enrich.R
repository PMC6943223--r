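#' Split called DEGs by direction
#'
#' @param degs a `deg_table` from [call_degs()].
#' @return List with character vectors `up` and `down`; `ns` genes are
#'   excluded, so the two sets partition the called DEGs.
#' @export
split_by_direction <- function(degs) {
  stopifnot(is.data.frame(degs), "call" %in% names(degs))
  list(up = degs$gene[degs$call == "up"],
       down = degs$gene[degs$call == "down"])
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher test per set from the 2x2 table of
#' in-set vs out-of-set by DEG vs non-DEG over the background universe;
#' the p-value equals the hypergeometric upper tail
#' `P(X >= overlap)`. BH FDR is applied across the sets of the
#' collection (i.e. within one direction x collection kind).
#' Significance follows the collection kind: `go_like` uses
#' `p <= p_max` (default 0.01) on the raw p-value, `pathway_like` uses
#' `fdr <= fdr_max` (default 0.05).
#'
#' @param deg_ids character vector of DEG ids (one direction); must be
#'   a subset of the collection's universe.
#' @param collection a [geneset_collection()].
#' @param direction label recorded in the result (`"up"` or `"down"`).
#' @param p_max raw-p significance cutoff for `go_like` collections.
#' @param fdr_max FDR significance cutoff for `pathway_like`
#'   collections.
#' @return Data.frame of class `enrichment_result`, sorted by p
#'   ascending with lexicographic set-id tie-break: `set_id`,
#'   `overlap_count`, `set_size`, `n_degs`, `universe_size`, `p_value`,
#'   `fdr`, `direction`, `significant`.
#' @export
fisher_enrich <- function(deg_ids, collection,
                          direction = c("up", "down"), p_max = 0.01,
                          fdr_max = 0.05) {
  direction <- match.arg(direction)
  stopifnot(inherits(collection, "geneset_collection"))
  deg_ids <- unique(deg_ids)
  missing <- setdiff(deg_ids, collection$universe)
  if (length(missing))
    stop2("DEG gene(s) absent from the universe: ",
          paste(utils::head(missing, 5), collapse = ", "))
  n_univ <- length(collection$universe)
  n_deg <- length(deg_ids)
  set_ids <- names(collection$sets)
  ov <- vapply(collection$sets, function(s)
    length(intersect(s, deg_ids)), integer(1))
  sz <- lengths(collection$sets)
  # upper tail P(X >= ov): white balls = DEGs, draws = set size
  p <- stats::phyper(ov - 1, n_deg, n_univ - n_deg, sz,
                     lower.tail = FALSE)
  fdr <- bh_adjust(p)
  sig <- if (collection$kind == "go_like") p <= p_max else
    fdr <= fdr_max
  out <- data.frame(set_id = set_ids, overlap_count = ov,
                    set_size = as.integer(sz), n_degs = n_deg,
                    universe_size = n_univ, p_value = p, fdr = fdr,
                    direction = direction, significant = sig,
                    row.names = NULL)
  out <- out[order_c(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "metadata") <- list(kind = collection$kind,
                                sidedness = "one-sided (greater)",
                                p_max = p_max, fdr_max = fdr_max)
  out
}
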