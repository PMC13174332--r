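# Shared internal helpers.

# Canonical JSON: recursively sort object keys, serialize with no
# insignificant whitespace, UTF-8, full numeric precision. Byte-identity of
# two documents is defined as equality of their canonical serializations.
canonical_json <- function(x) {
  jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm, method = "radix")]
    lapply(x, sort_keys)
  } else {
    x
  }
}

# Missing-label dialect: empty strings, NA, and the literal string "NA" all
# count as missing.
is_missing_label <- function(x) {
  is.na(x) | x == "" | x == "NA"
}

as_matrix <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

check_counts_matrix <- function(counts, arg = "counts") {
  if (is.null(dim(counts)) || length(dim(counts)) != 2L) {
    abort(sprintf("`%s` must be a cell x gene matrix", arg))
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort(sprintf("`%s` must have cell ids as rownames and gene ids as colnames", arg))
  }
  invisible(counts)
}

# radix-order for locale-independent, reproducible lexicographic ordering
lex_order <- function(...) order(..., method = "radix")
lex_sort <- function(x) sort(x, method = "radix")
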