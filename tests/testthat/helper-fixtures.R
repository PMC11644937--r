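# Small fixtures built in code; everything is seeded.

tiny_schema <- function() {
  table_schema(continuous = c("x", "y"), categorical = c("g", "h"))
}

tiny_table <- function(n = 40, seed = 11) {
  withr::with_seed(seed, tibble::tibble(
    x = c(rnorm(n %/% 2, 0, 1), rnorm(n - n %/% 2, 8, 1)),
    y = rnorm(n, 50, 5),
    g = sample(c("a", "b"), n, replace = TRUE, prob = c(0.7, 0.3)),
    h = sample(c("lo", "mid", "hi"), n, replace = TRUE)
  ))
}

tiny_transformer <- function(...) {
  fit_transformer(tiny_table(...), tiny_schema(), seed = 1)
}

# Hand-built transformer with exactly known mixture metadata, for condition
# sampling and codec tests that need controlled weights.
manual_transformer <- function(cont_metas, cat_metas = list(), cat_freqs = list()) {
  schema <- table_schema(
    continuous = names(cont_metas),
    categorical = lapply(cat_metas, `[[`, "categories"),
    order = c(names(cont_metas), names(cat_metas))
  )
  metas <- c(cont_metas, cat_metas)
  widths <- vapply(schema$column, function(col) {
    m <- metas[[col]]
    if (inherits(m, "continuous_meta")) 1L + m$n_modes else m$n_classes
  }, integer(1L))
  layout <- tibble::tibble(
    column = schema$column, kind = schema$kind,
    width = unname(widths), start = cumsum(c(1L, unname(widths)[-length(widths)]))
  )
  structure(list(schema = schema, metas = metas, layout = layout,
                 width = sum(widths), cat_freqs = cat_freqs),
            class = "table_transformer")
}

cont_meta <- function(means, stds, weights) {
  ehrsynth:::new_continuous_meta(means, stds, weights)
}

cat_meta <- function(categories) {
  structure(list(categories = categories, n_classes = length(categories)),
            class = "categorical_meta")
}

# Brute-force two-sample KS oracle: evaluate both ECDFs at every pooled point
# by explicit counting.
ks_oracle <- function(x, y) {
  pooled <- c(x, y)
  d <- 0
  for (t in pooled) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# Brute-force minibatch-discrimination oracle: double loop over rows/kernels.
minibatch_oracle <- function(X, kernel) {
  n <- nrow(X); B <- dim(kernel)[2L]; C <- dim(kernel)[3L]
  O <- matrix(0, n, B)
  for (i in seq_len(n)) {
    for (b in seq_len(B)) {
      Mi <- drop(X[i, ] %*% kernel[, b, ])
      s <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        Mj <- drop(X[j, ] %*% kernel[, b, ])
        s <- s + exp(-sum(abs(Mi - Mj)))
      }
      O[i, b] <- s
    }
  }
  cbind(X, O)
}
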