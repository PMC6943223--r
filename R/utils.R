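# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(name, " must be a single finite number")
  if (integer && x != round(x))
    stop2(name, " must be a whole number")
  if (x < min || x > max)
    stop2(name, " must be in [", min, ", ", max, "]")
  invisible(x)
}

# locale-independent ordering (C collation) so outputs are reproducible
order_c <- function(...) order(..., method = "radix")

# elementwise locale-independent x > y for character vectors
gt_c <- function(x, y) {
  if (!length(x)) return(logical(0))
  vapply(seq_along(x), function(i)
    x[i] != y[i] && order(c(x[i], y[i]), method = "radix")[1] == 2L,
    logical(1))
}

# tab-separated writer with fixed conventions so repeated runs are
# byte-identical
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", comment.char = "", ...)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
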