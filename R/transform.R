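#' Fit Gaussian-mixture metadata for a continuous column
#'
#' Each continuous column is modelled as a finite Gaussian mixture whose
#' component count adapts to the data: mixtures with 1 to `max_modes`
#' unequal-variance components are fitted (via \pkg{mclust}, with a variance
#' prior for stability on near-degenerate columns) and the best is kept by BIC.
#' Components with negligible weight are pruned and weights renormalized. The
#' means, standard deviations and weights of the surviving components are the
#' metadata later used for mode-specific normalization and for conditioning
#' the generator.
#'
#' @param values Numeric vector, all finite.
#' @param max_modes Maximum number of mixture components (default 10).
#' @param seed Integer seed; the fit is deterministic given `(values, max_modes, seed)`.
#' @param weight_floor Components with weight below this are pruned (default 1e-3).
#' @param sigma_floor Lower bound on component standard deviations (default 1e-6);
#'   also the standard deviation reported for constant columns.
#'
#' @return A `continuous_meta`: list with `means`, `stds`, `weights`, `n_modes`,
#'   plus the column's mixture-implied overall `mean` and `sd`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300), rnorm(300, 10))
#' meta <- fit_continuous_meta(x)
#' meta$n_modes
fit_continuous_meta <- function(values, max_modes = 10L, seed = 1L,
                                weight_floor = 1e-3, sigma_floor = 1e-6) {
  if (length(values) == 0L) stop("empty column", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite value", call. = FALSE)
  stopifnot(max_modes >= 1L)

  if (length(unique(values)) < 2L) {
    return(new_continuous_meta(means = values[1L], stds = sigma_floor, weights = 1))
  }

  fit <- withr::with_seed(as.integer(seed), suppressWarnings(
    Mclust(values, G = seq_len(max_modes), modelNames = "V",
           prior = priorControl(), verbose = FALSE)
  ))
  if (is.null(fit)) { # fall back to a single component
    return(new_continuous_meta(
      means = mean(values),
      stds = max(stats::sd(values), sigma_floor),
      weights = 1
    ))
  }
  means <- as.numeric(fit$parameters$mean)
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1L) vars <- rep(vars, length(means))
  stds <- pmax(sqrt(as.numeric(vars)), sigma_floor)
  weights <- as.numeric(fit$parameters$pro)

  keep <- weights >= weight_floor
  if (!any(keep)) keep <- which.max(weights)
  means <- means[keep]; stds <- stds[keep]; weights <- weights[keep]
  weights <- weights / sum(weights)
  ord <- order(means) # deterministic component order
  new_continuous_meta(means[ord], stds[ord], weights[ord])
}

new_continuous_meta <- function(means, stds, weights) {
  m <- sum(weights * means)
  v <- sum(weights * (stds^2 + means^2)) - m^2
  structure(
    list(means = means, stds = stds, weights = weights,
         n_modes = length(means), mean = m, sd = sqrt(max(v, 0))),
    class = "continuous_meta"
  )
}

#' @export
print.continuous_meta <- function(x, ...) {
  cat("<continuous_meta> ", x$n_modes, " mode(s)\n", sep = "")
  print(data.frame(mean = x$means, sd = x$stds, weight = x$weights))
  invisible(x)
}

# Per-component responsibilities of `values` under `meta`, computed in log space
# so far-tail points still yield a proper simplex. Returns an n x n_modes matrix.
responsibilities <- function(values, meta) {
  lp <- vapply(seq_len(meta$n_modes), function(k) {
    log(meta$weights[k]) + stats::dnorm(values, meta$means[k], meta$stds[k], log = TRUE)
  }, numeric(length(values)))
  lp <- matrix(lp, nrow = length(values))
  mx <- apply(lp, 1L, max)
  p <- exp(lp - mx)
  p / rowSums(p)
}

#' Mode-specific normalization of a continuous value
#'
#' Computes the posterior responsibility of each mixture component for `c`,
#' assigns the most responsible mode `k` (ties break to the lowest index), and
#' standardizes by that mode: `v = (c - mu_k) / sigma_k`, clipped to
#' `[-0.99, 0.99]` for numerical stability.
#'
#' @param c A finite numeric scalar (or vector, handled elementwise).
#' @param meta A [fit_continuous_meta()] result.
#' @return A list with `v` (clipped normalized value), `k` (1-based mode index)
#'   and `posterior` (matrix of responsibilities, one row per value).
#' @export
normalize_value <- function(c, meta) {
  if (any(!is.finite(c))) stop("non-finite value", call. = FALSE)
  post <- responsibilities(c, meta)
  k <- max.col(post, ties.method = "first")
  v <- (c - meta$means[k]) / meta$stds[k]
  list(v = pmin(pmax(v, -0.99), 0.99), k = k, posterior = post)
}

#' Invert mode-specific normalization
#'
#' @param v Normalized value(s) in `[-0.99, 0.99]`.
#' @param k Mode index/indices (1-based).
#' @param meta A [fit_continuous_meta()] result.
#' @return `v * sigma_k + mu_k`.
#' @export
denormalize_value <- function(v, k, meta) {
  if (any(k < 1L) || any(k > meta$n_modes)) stop("mode index out of range", call. = FALSE)
  v * meta$stds[k] + meta$means[k]
}

#' Fit categorical column metadata
#'
#' Categories are the sorted unique labels observed (lexicographic, for a
#' reproducible one-hot layout regardless of row order).
#'
#' @param values Vector of labels (coerced to character).
#' @return A `categorical_meta`: list with `categories` and `n_classes`.
#' @export
fit_categorical_meta <- function(values) {
  if (length(values) == 0L) stop("empty column", call. = FALSE)
  categories <- sort(unique(as.character(values)), method = "radix")
  structure(list(categories = categories, n_classes = length(categories)),
            class = "categorical_meta")
}

#' One-hot encode / decode a categorical value
#'
#' @param value A label present in `meta$categories`.
#' @param meta A [fit_categorical_meta()] result.
#' @return `encode_onehot()`: a 0/1 vector of length `n_classes`.
#' @export
encode_onehot <- function(value, meta) {
  idx <- match(as.character(value), meta$categories)
  if (anyNA(idx)) stop("unknown category: ", value[is.na(idx)][1L], call. = FALSE)
  out <- numeric(meta$n_classes)
  out[idx] <- 1
  out
}

#' @rdname encode_onehot
#' @param vector A non-negative vector of length `n_classes` with positive sum
#'   (one-hot or category probabilities).
#' @param mode `"argmax"` picks the largest entry (ties to the lowest index);
#'   `"sample"` draws a category proportionally to the entries.
#' @param seed Optional seed for `"sample"` mode.
#' @return `decode_onehot()`: a single category label.
#' @export
decode_onehot <- function(vector, meta, mode = c("argmax", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  if (length(vector) != meta$n_classes) stop("length mismatch", call. = FALSE)
  if (any(vector < 0) || sum(vector) <= 0) stop("entries must be >= 0 with positive sum", call. = FALSE)
  idx <- if (mode == "argmax") {
    which.max(vector)
  } else if (is.null(seed)) {
    sample.int(meta$n_classes, 1L, prob = vector)
  } else {
    withr::with_seed(as.integer(seed), sample.int(meta$n_classes, 1L, prob = vector))
  }
  meta$categories[idx]
}

#' Fit the full table transformer
#'
#' Fits per-column metadata ([fit_continuous_meta()] /
#' [fit_categorical_meta()]) for every schema column and records the flat
#' layout of the network representation: each continuous column contributes
#' `1 + n_modes` entries (clipped value followed by the one-hot mode
#' indicator), each categorical column contributes `n_classes` one-hot entries.
#' Empirical category frequencies are stored for condition sampling.
#'
#' @param data A data frame conforming to `schema`.
#' @param schema A [table_schema()].
#' @param max_modes,seed,weight_floor,sigma_floor Passed to [fit_continuous_meta()].
#' @param missing Passed to [check_table()].
#' @return A `table_transformer`: list with `schema`, `metas` (named list),
#'   `layout` (tibble of column/kind/start/width), `width`, and `cat_freqs`.
#' @export
fit_transformer <- function(data, schema, max_modes = 10L, seed = 1L,
                            weight_floor = 1e-3, sigma_floor = 1e-6,
                            missing = c("error", "drop_rows")) {
  data <- check_table(data, schema, missing = missing)
  if (nrow(data) == 0L) stop("empty column", call. = FALSE)
  metas <- list()
  cat_freqs <- list()
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (schema$kind[i] == "continuous") {
      metas[[col]] <- fit_continuous_meta(data[[col]], max_modes = max_modes,
                                          seed = seed, weight_floor = weight_floor,
                                          sigma_floor = sigma_floor)
    } else {
      vals <- as.character(data[[col]])
      lv <- schema$levels[[i]]
      meta <- if (is.null(lv)) fit_categorical_meta(vals) else
        structure(list(categories = lv, n_classes = length(lv)), class = "categorical_meta")
      metas[[col]] <- meta
      tab <- table(factor(vals, levels = meta$categories))
      cat_freqs[[col]] <- as.numeric(tab) / sum(tab)
    }
  }
  widths <- vapply(seq_len(nrow(schema)), function(i) {
    m <- metas[[schema$column[i]]]
    if (schema$kind[i] == "continuous") 1L + m$n_modes else m$n_classes
  }, integer(1L))
  layout <- tibble::tibble(
    column = schema$column, kind = schema$kind,
    width = widths, start = cumsum(c(1L, widths[-length(widths)]))
  )
  structure(list(schema = schema, metas = metas, layout = layout,
                 width = sum(widths), cat_freqs = cat_freqs),
            class = "table_transformer")
}

#' @export
print.table_transformer <- function(x, ...) {
  cat("<table_transformer> flat width ", x$width, " over ", nrow(x$schema),
      " columns\n", sep = "")
  print(x$layout)
  invisible(x)
}

#' Transform a table into its network representation
#'
#' Applies mode-specific normalization to continuous columns and one-hot
#' encoding to categorical columns, producing the flat numeric matrix the
#' generator emits and the critic consumes. Soft mode posteriors are kept
#' alongside; the flat matrix carries the hard (argmax) mode assignment.
#'
#' @param transformer A [fit_transformer()] result.
#' @param data A data frame conforming to the transformer's schema.
#' @param missing Passed to [check_table()].
#' @return A `transformed_table`: list with `values` (n x width matrix),
#'   `modes` (n x k integer matrix of assigned modes), `posteriors` (list of
#'   responsibility matrices per continuous column), and `layout`.
#' @export
transform_table <- function(transformer, data, missing = c("error", "drop_rows")) {
  data <- check_table(data, transformer$schema, missing = missing)
  n <- nrow(data)
  lay <- transformer$layout
  values <- matrix(0, nrow = n, ncol = transformer$width)
  cont_cols <- lay$column[lay$kind == "continuous"]
  modes <- matrix(0L, nrow = n, ncol = length(cont_cols),
                  dimnames = list(NULL, cont_cols))
  posteriors <- stats::setNames(vector("list", length(cont_cols)), cont_cols)

  for (i in seq_len(nrow(lay))) {
    col <- lay$column[i]
    meta <- transformer$metas[[col]]
    at <- lay$start[i]
    if (lay$kind[i] == "continuous") {
      if (n > 0L) {
        nv <- normalize_value(data[[col]], meta)
        values[, at] <- nv$v
        values[cbind(seq_len(n), at + nv$k)] <- 1
        modes[, col] <- nv$k
        posteriors[[col]] <- nv$posterior
      } else {
        posteriors[[col]] <- matrix(0, 0L, meta$n_modes)
      }
    } else if (n > 0L) {
      idx <- match(as.character(data[[col]]), meta$categories)
      if (anyNA(idx)) stop("unknown category in ", col, call. = FALSE)
      values[cbind(seq_len(n), at + idx - 1L)] <- 1
    }
  }
  structure(list(values = values, modes = modes, posteriors = posteriors,
                 layout = lay), class = "transformed_table")
}

#' Invert the network representation back to a table
#'
#' Continuous cells are denormalized with the mode carried in each row's
#' one-hot mode block; categorical blocks are decoded by `argmax` (default) or
#' proportional sampling.
#'
#' @param transformer A [fit_transformer()] result.
#' @param ttable A `transformed_table`, or a bare numeric matrix in the
#'   transformer's flat layout (e.g. raw generator output).
#' @param categorical `"argmax"` or `"sample"` decoding for categorical blocks.
#' @return A tibble conforming to the transformer's schema.
#' @export
inverse_transform_table <- function(transformer, ttable,
                                    categorical = c("argmax", "sample")) {
  categorical <- match.arg(categorical)
  values <- if (inherits(ttable, "transformed_table")) ttable$values else as.matrix(ttable)
  if (ncol(values) != transformer$width) {
    stop("matrix width ", ncol(values), " does not match layout width ",
         transformer$width, call. = FALSE)
  }
  n <- nrow(values)
  lay <- transformer$layout
  out <- vector("list", nrow(lay))
  names(out) <- lay$column
  for (i in seq_len(nrow(lay))) {
    col <- lay$column[i]
    meta <- transformer$metas[[col]]
    at <- lay$start[i]
    if (n == 0L) {
      out[[col]] <- if (lay$kind[i] == "continuous") numeric(0) else character(0)
      next
    }
    if (lay$kind[i] == "continuous") {
      v <- values[, at]
      onehot <- values[, at + seq_len(meta$n_modes), drop = FALSE]
      k <- max.col(onehot, ties.method = "first")
      out[[col]] <- denormalize_value(v, k, meta)
    } else {
      block <- values[, at + seq_len(meta$n_classes) - 1L, drop = FALSE]
      if (any(block < 0) || any(rowSums(block) <= 0)) {
        stop("malformed categorical block for ", col, call. = FALSE)
      }
      idx <- if (categorical == "argmax") {
        max.col(block, ties.method = "first")
      } else {
        vapply(seq_len(n), function(r) sample.int(meta$n_classes, 1L, prob = block[r, ]),
               integer(1L))
      }
      out[[col]] <- meta$categories[idx]
    }
  }
  tibble::as_tibble(out)
}

#' Serialize / restore transformer metadata as JSON
#'
#' Mixture means/standard deviations/weights and category vocabularies are
#' written as plain JSON so fitted transforms are portable across sessions.
#'
#' @param transformer A [fit_transformer()] result.
#' @param path File path.
#' @return `write_transformer_json()` returns `path` invisibly;
#'   `read_transformer_json()` returns a `table_transformer`.
#' @export
write_transformer_json <- function(transformer, path) {
  sch <- transformer$schema
  metas <- lapply(seq_len(nrow(sch)), function(i) {
    m <- transformer$metas[[sch$column[i]]]
    if (sch$kind[i] == "continuous") {
      list(kind = "continuous", means = m$means, stds = m$stds, weights = m$weights)
    } else {
      list(kind = "categorical", categories = m$categories,
           frequencies = transformer$cat_freqs[[sch$column[i]]])
    }
  })
  names(metas) <- sch$column
  jsonlite::write_json(list(columns = metas), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transformer_json
#' @export
read_transformer_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)$columns
  kinds <- vapply(cfg, `[[`, character(1L), "kind")
  schema <- table_schema(
    continuous = names(cfg)[kinds == "continuous"],
    categorical = stats::setNames(
      lapply(cfg[kinds == "categorical"], `[[`, "categories"),
      names(cfg)[kinds == "categorical"]
    ),
    order = names(cfg)
  )
  metas <- list(); cat_freqs <- list()
  for (col in names(cfg)) {
    m <- cfg[[col]]
    if (m$kind == "continuous") {
      metas[[col]] <- new_continuous_meta(as.numeric(m$means), as.numeric(m$stds),
                                          as.numeric(m$weights))
    } else {
      metas[[col]] <- structure(
        list(categories = as.character(m$categories), n_classes = length(m$categories)),
        class = "categorical_meta")
      cat_freqs[[col]] <- as.numeric(m$frequencies)
    }
  }
  widths <- vapply(names(cfg), function(col) {
    if (kinds[[col]] == "continuous") 1L + metas[[col]]$n_modes else metas[[col]]$n_classes
  }, integer(1L))
  layout <- tibble::tibble(
    column = names(cfg), kind = unname(kinds),
    width = unname(widths), start = cumsum(c(1L, unname(widths)[-length(widths)]))
  )
  structure(list(schema = schema, metas = metas, layout = layout,
                 width = sum(widths), cat_freqs = cat_freqs),
            class = "table_transformer")
}
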