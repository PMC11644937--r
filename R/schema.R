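#' Declare a mixed-type table schema
#'
#' A schema records, in order, which columns of a patient table are continuous
#' and which are categorical. Categorical vocabularies may be declared up front
#' (a named list of level vectors) or left `NULL` to be learned from data when
#' a transformer is fitted.
#'
#' @param continuous Character vector of continuous column names.
#' @param categorical Either a character vector of categorical column names, or
#'   a named list mapping column names to their ordered category labels.
#' @param order Optional character vector giving the display order of all
#'   columns; defaults to continuous first, then categorical.
#'
#' @return A `table_schema`: a tibble with columns `column`, `kind`
#'   (`"continuous"` or `"categorical"`) and `levels` (list column).
#' @export
#' @examples
#' table_schema(continuous = c("Age", "BMI"), categorical = c("Gender", "HTN"))
table_schema <- function(continuous = character(), categorical = character(),
                         order = NULL) {
  if (is.list(categorical)) {
    cat_names <- names(categorical)
    cat_levels <- lapply(categorical, function(x) {
      x <- as.character(x)
      if (anyDuplicated(x) || length(x) < 1L) {
        stop("categorical specs need >= 1 unique category", call. = FALSE)
      }
      x
    })
  } else {
    cat_names <- as.character(categorical)
    cat_levels <- rep(list(NULL), length(cat_names))
  }
  continuous <- as.character(continuous)
  all_names <- c(continuous, cat_names)
  if (length(all_names) < 1L) stop("schema needs at least one column", call. = FALSE)
  if (any(!nzchar(all_names))) stop("column names must be non-empty", call. = FALSE)
  if (anyDuplicated(all_names)) stop("column names must be unique", call. = FALSE)

  out <- tibble::tibble(
    column = all_names,
    kind   = c(rep("continuous", length(continuous)), rep("categorical", length(cat_names))),
    levels = c(rep(list(NULL), length(continuous)), cat_levels)
  )
  if (!is.null(order)) {
    if (!setequal(order, all_names)) stop("`order` must permute the column names", call. = FALSE)
    out <- out[match(order, out$column), ]
  }
  structure(out, class = c("table_schema", class(tibble::tibble())))
}

#' @export
print.table_schema <- function(x, ...) {
  cat("<table_schema> ", sum(x$kind == "continuous"), " continuous + ",
      sum(x$kind == "categorical"), " categorical columns\n", sep = "")
  NextMethod()
}

schema_continuous <- function(schema) schema$column[schema$kind == "continuous"]
schema_categorical <- function(schema) schema$column[schema$kind == "categorical"]

#' Validate a data frame against a schema
#'
#' Checks that all schema columns are present, continuous columns are finite
#' numeric, and categorical values fall in the declared vocabulary (when one is
#' declared). Missing values either raise an error (default) or cause the
#' offending rows to be dropped.
#'
#' @param data A data frame of patient records.
#' @param schema A [table_schema()].
#' @param missing One of `"error"` or `"drop_rows"`.
#' @return The validated data as a tibble (rows possibly dropped), columns in
#'   schema order.
#' @export
check_table <- function(data, schema, missing = c("error", "drop_rows")) {
  missing <- match.arg(missing)
  stopifnot(is.data.frame(data))
  absent <- setdiff(schema$column, names(data))
  if (length(absent)) {
    stop("columns missing from data: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)[schema$column]
  has_na <- !stats::complete.cases(data)
  if (any(has_na)) {
    if (missing == "error") {
      stop("missing values in rows: ", paste(utils::head(which(has_na), 5L), collapse = ", "),
           " (use missing = \"drop_rows\" to drop them)", call. = FALSE)
    }
    data <- data[!has_na, ]
  }
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    vals <- data[[col]]
    if (schema$kind[i] == "continuous") {
      if (!is.numeric(vals)) stop("continuous column not numeric: ", col, call. = FALSE)
      if (nrow(data) && any(!is.finite(vals))) stop("non-finite value in column: ", col, call. = FALSE)
    } else {
      lv <- schema$levels[[i]]
      if (!is.null(lv) && nrow(data)) {
        bad <- setdiff(unique(as.character(vals)), lv)
        if (length(bad)) {
          stop("unknown category in ", col, ": ", paste(bad, collapse = ", "), call. = FALSE)
        }
      }
    }
  }
  data
}

#' Read / write a column-kind configuration (YAML)
#'
#' The configuration is a YAML mapping `columns: {name: continuous|categorical}`,
#' the format the command-line interface consumes.
#'
#' @param path File path.
#' @return `read_schema_yaml()` returns a [table_schema()];
#'   `write_schema_yaml()` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$columns)) stop("config must contain a `columns:` mapping", call. = FALSE)
  kinds <- unlist(cfg$columns)
  bad <- setdiff(unique(kinds), c("continuous", "categorical"))
  if (length(bad)) stop("unknown column kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  table_schema(
    continuous = names(kinds)[kinds == "continuous"],
    categorical = names(kinds)[kinds == "categorical"],
    order = names(kinds)
  )
}

#' @rdname read_schema_yaml
#' @param schema A [table_schema()].
#' @export
write_schema_yaml <- function(schema, path) {
  kinds <- as.list(stats::setNames(schema$kind, schema$column))
  yaml::write_yaml(list(columns = kinds), path)
  invisible(path)
}
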