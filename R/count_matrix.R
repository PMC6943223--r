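#' Construct a two-condition count matrix
#'
#' The single entry point of the pipeline: a gene x sample matrix of
#' non-negative integer read counts together with a condition label per
#' sample. Exactly two conditions are allowed, each with at least two
#' replicates; the first factor level is the reference (condition A,
#' e.g. control) and the second is the comparison (condition B, e.g.
#' treatment), so downstream fold changes read B over A.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param condition character or factor of length `ncol(counts)` mapping
#'   each sample to one of two condition labels.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `condition` (a two-level factor named by sample).
#' @export
count_matrix <- function(counts, condition) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop2("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop2("duplicate sample ids in counts")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop2("counts must be finite numbers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("counts must be non-negative integers")
  storage.mode(counts) <- "double"   # keeps large totals exact enough
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts))
    stop2("condition must have one label per sample")
  if (nlevels(condition) != 2L)
    stop2("exactly two conditions are required, got ",
          nlevels(condition))
  if (any(table(condition) < 2L))
    stop2("each condition needs at least 2 replicate samples")
  names(condition) <- colnames(counts)
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tb <- table(x$condition)
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", paste(names(tb), tb, sep = "=", collapse = ", "),
      ")\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

cm_condition_levels <- function(cm) levels(cm$condition)

cm_samples <- function(cm, condition) {
  names(cm$condition)[cm$condition == condition]
}

#' Write / read a count matrix as TSV
#'
#' The matrix file has a `gene` id first column and one column per sample;
#' the companion condition map is a two-column TSV (`sample`, `condition`).
#'
#' @param cm a [count_matrix()].
#' @param counts_path,conditions_path output file paths.
#' @name count_matrix_io
#' @export
write_count_matrix <- function(cm, counts_path, conditions_path) {
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, counts_path)
  write_tsv(data.frame(sample = names(cm$condition),
                       condition = as.character(cm$condition)),
            conditions_path)
  invisible(cm)
}

#' @param ... passed to the constructor.
#' @rdname count_matrix_io
#' @export
read_count_matrix <- function(counts_path, conditions_path, ...) {
  df <- read_tsv(counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cond <- read_tsv(conditions_path)
  idx <- match(colnames(m), cond$sample)
  if (anyNA(idx))
    stop2("samples missing from condition map: ",
          paste(colnames(m)[is.na(idx)], collapse = ", "))
  count_matrix(m, cond$condition[idx], ...)
}
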