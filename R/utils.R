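# Shared internal helpers: condition signalling and stable JSON output.

fq_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("fqcross_error_", class), "fqcross_error"), ...)
}

fq_assert <- function(cond, message, class) {
  if (!isTRUE(cond)) fq_abort(message, class)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Residue identity as a stable key: "chain:resseq".
residue_key <- function(chain, resseq) paste(chain, resseq, sep = ":")

#' Write a list as deterministic JSON
#'
#' Keys are sorted recursively and floating point numbers are rendered with six
#' significant digits so that repeated runs on identical inputs produce
#' byte-identical files.
#'
#' @param x A (possibly nested) named list of scalars, vectors and data frames.
#' @param path File to write. When `NULL` the JSON string is returned invisibly.
#' @return The JSON string, invisibly.
#' @export
write_stable_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = I(6),
                           dataframe = "columns", null = "null", na = "null")
  if (!is.null(path)) writeLines(json, path, useBytes = TRUE)
  invisible(as.character(json))
}

sort_keys <- function(x) {
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    x <- lapply(x, sort_keys)
  }
  x
}
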