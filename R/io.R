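#' Read a patient table from CSV according to a schema
#'
#' Continuous columns are read as doubles, categorical columns as character.
#'
#' @param path CSV file with a header row.
#' @param schema A [table_schema()].
#' @param missing Passed to [check_table()].
#' @return A validated tibble in schema column order.
#' @export
read_table_csv <- function(path, schema, missing = c("error", "drop_rows")) {
  types <- stats::setNames(
    ifelse(schema$kind == "continuous", "d", "c"), schema$column)
  data <- readr::read_csv(path, col_types = do.call(readr::cols, as.list(types)),
                          progress = FALSE)
  check_table(data, schema, missing = missing)
}

#' @rdname read_table_csv
#' @param data A data frame conforming to `schema`.
#' @export
write_table_csv <- function(data, path, schema = NULL) {
  if (!is.null(schema)) data <- check_table(data, schema)
  readr::write_csv(data, path)
  invisible(path)
}
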