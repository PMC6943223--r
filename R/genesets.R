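#' Gene-set collection over a background universe
#'
#' @param sets named list of character vectors (member gene ids).
#' @param universe character vector of background gene ids; every set
#'   member must belong to it.
#' @param kind `"go_like"` (term significance on raw Fisher p <= 0.01)
#'   or `"pathway_like"` (significance on FDR <= 0.05).
#' @param enriched_set_ids optional ids of sets planted as enriched
#'   (ground-truth bookkeeping for synthetic collections).
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets, universe,
                               kind = c("go_like", "pathway_like"),
                               enriched_set_ids = character(0)) {
  kind <- match.arg(kind)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop2("sets must have unique names")
  if (any(lengths(sets) == 0))
    stop2("empty gene sets are not allowed")
  if (anyDuplicated(universe))
    stop2("duplicate gene ids in universe")
  outside <- setdiff(unique(unlist(sets)), universe)
  if (length(outside))
    stop2("set members outside the universe: ",
          paste(utils::head(outside, 5), collapse = ", "))
  structure(list(sets = lapply(sets, unique), universe = universe,
                 kind = kind, enriched_set_ids = enriched_set_ids),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("geneset_collection (", x$kind, "): ", length(x$sets),
      " sets over ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids.
#'
#' @param collection a [geneset_collection()].
#' @param path file path.
#' @name gmt_io
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' @param universe background gene ids for the read collection; defaults
#'   to the union of all members.
#' @param ... passed to [geneset_collection()].
#' @rdname gmt_io
#' @export
read_gmt <- function(path, universe = NULL, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  geneset_collection(sets, universe, ...)
}
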