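#' The closed KEGG-style relation-type vocabulary
#'
#' `act` activation/phosphorylation, `inh` inhibition, `bin`
#' binding/association, `com` compound, `exp` expression, plus
#' `dissociation`. `bin` and `com` are treated as undirected; the other
#' four as directed.
#'
#' @return Character vector of the six type labels.
#' @export
relation_types <- function() {
  c("act", "inh", "bin", "com", "exp", "dissociation")
}

undirected_types <- function() c("bin", "com")

#' Typed relation table between genes or pathways
#'
#' @param df data.frame with columns `source`, `target`, `type`; an
#'   optional logical `directed` column is recomputed from the type
#'   semantics if absent.
#' @return A validated data.frame of class `relation_table` with columns
#'   `source`, `target`, `type`, `directed`.
#' @export
relation_table <- function(df) {
  need <- c("source", "target", "type")
  if (!all(need %in% names(df)))
    stop2("relation table needs columns: ",
          paste(need, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$type), relation_types())
  if (length(bad))
    stop2("unknown relation type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df[need]))
    stop2("duplicate (source, target, type) triples")
  df$directed <- !(df$type %in% undirected_types())
  rownames(df) <- NULL
  class(df) <- c("relation_table", "data.frame")
  df
}

#' Read and write relation tables as TSV
#'
#' Columns: `source`, `target`, `type`, `direction`
#' (`directed`/`undirected`).
#'
#' @param rel a [relation_table()].
#' @param path file path.
#' @name relation_io
#' @export
write_relations <- function(rel, path) {
  out <- data.frame(source = rel$source, target = rel$target,
                    type = rel$type,
                    direction = ifelse(rel$directed, "directed",
                                       "undirected"))
  write_tsv(out, path)
}

#' @rdname relation_io
#' @export
read_relations <- function(path) {
  df <- read_tsv(path)
  relation_table(df[c("source", "target", "type")])
}
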