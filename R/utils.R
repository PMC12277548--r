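# Internal helpers: error classes and seed substreams.

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("areascan_invalid_input", "areascan_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("areascan_degenerate_input", "areascan_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("areascan_config_error", "areascan_error")))
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid("non-finite values in %s", what)
}

#' Derive a named seed substream from a root seed
#'
#' All randomness in the pipeline flows from one root seed; each stage
#' draws from its own substream so stages can be re-run individually
#' without disturbing one another. The substream is a deterministic hash
#' of the root seed and the stage name, kept within the 32-bit integer
#' range R requires of `set.seed()`.
#'
#' @param seed integer root seed.
#' @param stream character stage name.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# write a TSV with a JSON sidecar schema so stage outputs are
# self-describing and round-trip checkable
write_tsv_schema <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- list(
    columns = lapply(seq_along(df), function(i) {
      list(name = names(df)[i], type = class(df[[i]])[1])
    }),
    n_rows = nrow(df)
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

read_tsv_checked <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  schema_path <- paste0(path, ".schema.json")
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path)
    want <- vapply(schema$columns, function(x) x$name, character(1))
    if (!identical(names(df), want))
      stop_invalid("columns of %s do not match sidecar schema", path)
    if (nrow(df) != schema$n_rows)
      stop_invalid("row count of %s does not match sidecar schema", path)
  }
  df
}
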