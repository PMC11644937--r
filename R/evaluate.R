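#' Two-sample Kolmogorov–Smirnov statistic
#'
#' The supremum over the pooled sample points of the absolute difference
#' between the two right-continuous empirical CDFs. Ties are handled exactly by
#' evaluating at every pooled point. Ranges in `[0, 1]`; 0 means identical
#' empirical distributions, 1 disjoint supports.
#'
#' @param x,y Non-empty numeric samples.
#' @return The KS statistic, a scalar in `[0, 1]`.
#' @export
#' @examples
#' ks_statistic(c(1, 2), c(1, 3)) # 0.5
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(pooled) - stats::ecdf(y)(pooled)))
}

#' Jaccard similarity of observed category sets
#'
#' `|A intersect B| / |A union B|` where `A` and `B` are the sets of distinct
#' labels observed in the real and synthetic columns. 1 means the synthetic
#' column reproduces exactly the categories present in the real data.
#'
#' @param real_col,synth_col Non-empty label vectors.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' jaccard_categories(c("a", "b"), c("b", "c")) # 1/3
jaccard_categories <- function(real_col, synth_col) {
  if (!length(real_col) || !length(synth_col)) stop("empty column", call. = FALSE)
  a <- unique(as.character(real_col))
  b <- unique(as.character(synth_col))
  length(intersect(a, b)) / length(union(a, b))
}

#' Pearson correlation preservation rate
#'
#' Computes Pearson correlation matrices over the shared continuous columns of
#' the real and synthetic tables; a pair `(i < j)` is preserved when
#' `|r_real - r_synth| <= tau`. Returns the preserved percentage. Constant
#' columns are excluded with a warning (their correlations are undefined).
#'
#' @param real,synth Data frames with the same continuous columns.
#' @param tau Absolute correlation-difference tolerance (default 0.1).
#' @param columns Optional character vector naming the continuous columns;
#'   defaults to all shared numeric columns.
#' @return Percentage of preserved pairs (0–100).
#' @export
correlation_preservation_rate <- function(real, synth, tau = 0.1, columns = NULL) {
  cp <- correlation_pair(real, synth, tau, columns)
  cp$rate
}

correlation_pair <- function(real, synth, tau, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(names(real)[vapply(real, is.numeric, logical(1L))],
                         names(synth)[vapply(synth, is.numeric, logical(1L))])
  }
  keep <- columns[vapply(columns, function(cl) {
    ok <- stats::sd(real[[cl]]) > 0 && stats::sd(synth[[cl]]) > 0
    if (!ok) warning("constant column excluded: ", cl, call. = FALSE)
    ok
  }, logical(1L))]
  if (length(keep) < 2L) stop("need >= 2 non-constant continuous columns", call. = FALSE)
  if (nrow(real) < 3L || nrow(synth) < 3L) stop("need >= 3 rows", call. = FALSE)
  r_real <- stats::cor(as.data.frame(real)[keep])
  r_synth <- stats::cor(as.data.frame(synth)[keep])
  diffs <- abs(r_real - r_synth)[upper.tri(r_real)]
  list(rate = 100 * mean(diffs <= tau), cor_real = r_real, cor_synth = r_synth,
       columns = keep)
}

#' Evaluate synthetic-data fidelity
#'
#' Compares a synthetic table against the real table it emulates: per-column
#' two-sample KS statistics (continuous, on the raw scale), their mean,
#' per-column Jaccard similarity of observed category sets (categorical), and
#' the Pearson correlation preservation rate over continuous pairs.
#'
#' @param real,synth Data frames sharing `schema`.
#' @param schema A [table_schema()].
#' @param tau Correlation-preservation tolerance (default 0.1; always reported).
#' @return A `fidelity_report`: list with `continuous` (tibble of column/ks),
#'   `categorical` (tibble of column/jaccard), `mean_ks`, `preservation_rate`,
#'   `cor_real`, `cor_synth`, `tau`, `n_real`, `n_synth`.
#' @export
#' @examples
#' cohort <- simulate_cohort(n = 60, seed = 3)
#' rep <- evaluate_fidelity(cohort, cohort, cohort_schema())
#' rep$mean_ks # 0: self-comparison
evaluate_fidelity <- function(real, synth, schema, tau = 0.1) {
  real <- check_table(real, schema)
  synth <- check_table(synth, schema)
  cont <- schema_continuous(schema)
  cate <- schema_categorical(schema)
  ks <- vapply(cont, function(cl) ks_statistic(real[[cl]], synth[[cl]]), numeric(1L))
  jac <- vapply(cate, function(cl) jaccard_categories(real[[cl]], synth[[cl]]), numeric(1L))
  cp <- if (length(cont) >= 2L) correlation_pair(real, synth, tau, cont) else
    list(rate = NA_real_, cor_real = NULL, cor_synth = NULL)
  structure(list(
    continuous = tibble::tibble(column = cont, ks = unname(ks)),
    categorical = tibble::tibble(column = cate, jaccard = unname(jac)),
    mean_ks = mean(ks),
    preservation_rate = cp$rate,
    cor_real = cp$cor_real, cor_synth = cp$cor_synth,
    tau = tau, n_real = nrow(real), n_synth = nrow(synth)
  ), class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> ", x$n_real, " real vs ", x$n_synth, " synthetic rows\n",
      sep = "")
  cat(sprintf("mean KS = %.4f over %d continuous columns\n", x$mean_ks,
              nrow(x$continuous)))
  if (nrow(x$categorical)) {
    cat(sprintf("Jaccard = 1 for %d / %d categorical columns\n",
                sum(x$categorical$jaccard == 1), nrow(x$categorical)))
  }
  if (!is.na(x$preservation_rate)) {
    cat(sprintf("correlation preservation = %.2f%% (tau = %.2f)\n",
                x$preservation_rate, x$tau))
  }
  invisible(x)
}

#' Export distribution data behind CDF and frequency plots
#'
#' Writes, per continuous column, a CSV of `(value, cdf_real, cdf_synth)` at
#' the pooled sample points, and per categorical column a CSV of
#' `(category, n_real, n_synth)`.
#'
#' @param real,synth Non-empty data frames sharing `schema`.
#' @param schema A [table_schema()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_distribution_data <- function(real, synth, schema, dir) {
  real <- check_table(real, schema)
  synth <- check_table(synth, schema)
  if (!nrow(real) || !nrow(synth)) stop("empty table", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  files <- character(0)
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    path <- file.path(dir, paste0(
      if (schema$kind[i] == "continuous") "cdf_" else "freq_", safe(col), ".csv"))
    if (schema$kind[i] == "continuous") {
      pooled <- sort(unique(c(real[[col]], synth[[col]])))
      out <- tibble::tibble(value = pooled,
                            cdf_real = stats::ecdf(real[[col]])(pooled),
                            cdf_synth = stats::ecdf(synth[[col]])(pooled))
    } else {
      lev <- sort(union(unique(as.character(real[[col]])),
                        unique(as.character(synth[[col]]))))
      out <- tibble::tibble(
        category = lev,
        n_real = as.integer(table(factor(real[[col]], levels = lev))),
        n_synth = as.integer(table(factor(synth[[col]], levels = lev)))
      )
    }
    readr::write_csv(out, path)
    files <- c(files, path)
  }
  invisible(files)
}

#' Write a fidelity report as JSON
#'
#' @param report A [evaluate_fidelity()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    mean_ks = report$mean_ks,
    preservation_rate = report$preservation_rate,
    tau = report$tau,
    n_real = report$n_real, n_synth = report$n_synth,
    ks = as.list(stats::setNames(report$continuous$ks, report$continuous$column)),
    jaccard = as.list(stats::setNames(report$categorical$jaccard,
                                      report$categorical$column))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
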