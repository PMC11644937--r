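test_that("mixture metadata fitting handles degenerate and well-separated columns", {
  # constant column: one mode at the value, floored standard deviation
  meta <- fit_continuous_meta(c(5, 5, 5, 5))
  expect_equal(meta$n_modes, 1L)
  expect_equal(meta$means, 5)
  expect_equal(meta$stds, 1e-6)
  expect_equal(meta$weights, 1)

  expect_error(fit_continuous_meta(numeric(0)), "empty column")
  expect_error(fit_continuous_meta(c(1, NaN)), "non-finite value")

  # recovery of a seeded equal-weight two-component simulation
  x <- withr::with_seed(101, c(rnorm(500, 0, 1), rnorm(500, 10, 1)))
  meta <- fit_continuous_meta(x, max_modes = 10, seed = 1)
  expect_equal(meta$n_modes, 2L)
  expect_lt(max(abs(sort(meta$means) - c(0, 10))), 0.2)
  expect_lt(max(abs(meta$weights - 0.5)), 0.05)

  # normalization invariant and determinism
  expect_equal(sum(meta$weights), 1, tolerance = 1e-6)
  meta2 <- fit_continuous_meta(x, max_modes = 10, seed = 1)
  expect_identical(meta, meta2)
})

test_that("mode-specific normalization matches hand-computed values and clips", {
  meta <- cont_meta(8, 2, 1)
  expect_equal(normalize_value(8, meta)$v, 0)
  expect_equal(normalize_value(9, meta)$v, 0.5)   # (9 - 8) / 2
  expect_equal(normalize_value(20, meta)$v, 0.99) # clipped
  expect_equal(normalize_value(-20, meta)$v, -0.99)
  expect_equal(normalize_value(9, meta)$k, 1L)
  expect_error(normalize_value(NA_real_, meta), "non-finite")

  # posteriors are a simplex even far in the tails
  meta2 <- cont_meta(c(0, 10), c(1, 1), c(0.5, 0.5))
  post <- normalize_value(c(-50, 5, 50), meta2)$posterior
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-6)
  expect_equal(normalize_value(-50, meta2)$k, 1L)
  expect_equal(normalize_value(50, meta2)$k, 2L)
})

test_that("denormalization inverts normalization wherever clipping does not bind", {
  meta <- cont_meta(8, 2, 1)
  expect_equal(denormalize_value(0, 1, meta), 8)
  expect_equal(denormalize_value(0.5, 1, meta), 9)
  expect_error(denormalize_value(0.5, 3, meta), "out of range")

  meta2 <- cont_meta(c(-3, 4), c(0.5, 2), c(0.4, 0.6))
  vals <- withr::with_seed(7, c(rnorm(200, -3, 0.5), rnorm(200, 4, 2)))
  nv <- normalize_value(vals, meta2)
  ok <- abs(nv$v) < 0.99
  expect_gt(sum(ok), 0)
  expect_equal(denormalize_value(nv$v[ok], nv$k[ok], meta2), vals[ok], tolerance = 1e-9)
})

test_that("one-hot codec round-trips and rejects unseen labels", {
  meta <- fit_categorical_meta(c("b", "a", "b"))
  expect_equal(meta$categories, c("a", "b"))
  expect_equal(meta$n_classes, 2L)
  expect_equal(fit_categorical_meta(c("x", "x"))$n_classes, 1L)
  expect_error(fit_categorical_meta(character(0)), "empty column")

  expect_equal(encode_onehot("a", meta), c(1, 0))
  expect_equal(encode_onehot("b", meta), c(0, 1))
  expect_error(encode_onehot("z", meta), "unknown category")

  expect_equal(decode_onehot(c(0, 1), meta), "b")
  expect_equal(decode_onehot(c(0.5, 0.5), meta), "a") # ties to lowest index
  expect_equal(decode_onehot(c(1, 0), meta, mode = "sample", seed = 3), "a")
  expect_error(decode_onehot(c(1, 0, 0), meta), "length mismatch")
  # seeded sampling is deterministic and follows the probabilities
  draws <- vapply(1:200, function(i) decode_onehot(c(0.2, 0.8), meta,
                                                   mode = "sample", seed = i),
                  character(1))
  expect_identical(draws, vapply(1:200, function(i) decode_onehot(c(0.2, 0.8), meta,
                                                                  mode = "sample", seed = i),
                                 character(1)))
  expect_gt(mean(draws == "b"), 0.6)
})

test_that("table transform has the contracted width and inverts exactly", {
  tab <- tiny_table()
  tr <- tiny_transformer()
  # width = sum over continuous of (1 + n_modes) + sum over categorical of n_classes
  k_modes <- vapply(c("x", "y"), function(cl) tr$metas[[cl]]$n_modes, integer(1))
  expect_equal(tr$width, sum(1L + k_modes) + 2L + 3L)

  tt <- transform_table(tr, tab)
  expect_equal(nrow(tt$values), nrow(tab))
  v_idx <- tr$layout$start[tr$layout$kind == "continuous"]
  expect_lte(max(abs(tt$values[, v_idx])), 0.99)
  # every one-hot block has exactly one 1
  for (i in which(tr$layout$kind == "categorical")) {
    block <- tt$values[, tr$layout$start[i] + seq_len(tr$layout$width[i]) - 1L]
    expect_true(all(rowSums(block) == 1))
  }
  for (p in tt$posteriors) expect_equal(rowSums(p), rep(1, nrow(tab)), tolerance = 1e-6)

  back <- inverse_transform_table(tr, tt)
  unclipped <- apply(abs(tt$values[, v_idx, drop = FALSE]) < 0.99, 1, all)
  expect_equal(as.data.frame(back[unclipped, ]), as.data.frame(tab[unclipped, ]),
               tolerance = 1e-9)

  # empty table: correct width, zero rows, empty inverse
  empty <- tab[0, ]
  tt0 <- transform_table(tr, empty)
  expect_equal(dim(tt0$values), c(0L, tr$width))
  expect_equal(nrow(inverse_transform_table(tr, tt0)), 0L)

  expect_error(inverse_transform_table(tr, matrix(0, 2, tr$width + 1)), "width")
})

test_that("a hand-built transformed row inverts to the expected record", {
  tr <- manual_transformer(list(x = cont_meta(8, 2, 1)), list(g = cat_meta(c("a", "b"))))
  row <- matrix(c(0.5, 1, 0, 1), nrow = 1) # v = 0.5, mode 1, one-hot "b"
  back <- inverse_transform_table(tr, row)
  expect_equal(back$x, 9)
  expect_equal(back$g, "b")
})

test_that("transformer metadata survives a JSON round trip", {
  tr <- tiny_transformer()
  path <- withr::local_tempfile(fileext = ".json")
  write_transformer_json(tr, path)
  back <- read_transformer_json(path)
  expect_equal(back$width, tr$width)
  expect_equal(back$layout, tr$layout)
  expect_equal(back$metas$x$means, tr$metas$x$means)
  expect_equal(back$metas$g$categories, tr$metas$g$categories)
  expect_equal(back$cat_freqs, tr$cat_freqs)
  # and it still transforms identically
  tab <- tiny_table()
  expect_equal(transform_table(back, tab)$values, transform_table(tr, tab)$values)
})
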