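test_that("condition sampling follows mixture weights and category frequencies", {
  tr <- manual_transformer(
    list(a = cont_meta(c(0, 10), c(1, 1), c(0.5, 0.5)),
         b = cont_meta(5, 1, 1),
         c = cont_meta(c(0, 10), c(1, 1), c(1, 0))),
    list(g = cat_meta(c("x", "y"))),
    cat_freqs = list(g = c(0.8, 0.2))
  )
  cond <- sample_condition(tr, n = 10000, seed = 21)
  expect_equal(mean(cond$cont$a == 1L), 0.5, tolerance = 0.02)
  expect_true(all(cond$cont$b == 1L))   # single mode
  expect_true(all(cond$cont$c == 1L))   # zero-weight mode never selected
  expect_equal(mean(cond$cat$g == 1L), 0.8, tolerance = 0.02)
  expect_identical(cond, sample_condition(tr, n = 10000, seed = 21))

  expect_error(sample_condition(tr, 5, frequencies = list(g = c(1, 0, 0))),
               "length mismatch")
})

test_that("generator output respects the transformed-layout contracts", {
  tr <- tiny_transformer()
  gen <- build_generator(tr, generator_spec(z_dim = 32), seed = 13)

  n <- 64
  cond <- sample_condition(tr, n, seed = 1)
  Z <- withr::with_seed(2, matrix(rnorm(n * 32), n, 32))
  fw <- ehrsynth:::generator_forward(gen, Z, cond, training = FALSE)
  rows <- fw$rows

  # width contract: generator output width equals the transform layout width
  expect_equal(ncol(rows), tr$width)

  lay <- tr$layout
  for (i in seq_len(nrow(lay))) {
    at <- lay$start[i]
    meta <- tr$metas[[lay$column[i]]]
    if (lay$kind[i] == "continuous") {
      # bounded head keeps continuous outputs inside the clip range
      expect_true(all(abs(rows[, at]) <= 0.99))
      # the conditioned mode one-hot is passed through, not re-predicted
      onehot <- rows[, at + seq_len(meta$n_modes), drop = FALSE]
      expect_equal(max.col(onehot), cond$cont[[lay$column[i]]])
      expect_true(all(onehot %in% c(0, 1)))
    } else {
      block <- rows[, at + seq_len(meta$n_classes) - 1L, drop = FALSE]
      expect_equal(rowSums(block), rep(1, n), tolerance = 1e-5)
      expect_true(all(block >= 0))
    }
  }
})

test_that("generated tables conform to the schema and are seed-deterministic", {
  tr <- tiny_transformer()
  gen <- build_generator(tr, seed = 3)

  tab <- generate_table(gen, 50, seed = 17)
  expect_equal(nrow(tab), 50L)
  expect_named(tab, tr$schema$column)
  expect_true(all(tab$g %in% tr$metas$g$categories))
  expect_true(all(tab$h %in% tr$metas$h$categories))

  # decoded continuous values stay within the conditioned-mode reach
  for (cl in c("x", "y")) {
    m <- tr$metas[[cl]]
    expect_gte(min(tab[[cl]]), min(m$means - 0.99 * m$stds))
    expect_lte(max(tab[[cl]]), max(m$means + 0.99 * m$stds))
  }

  expect_identical(tab, generate_table(gen, 50, seed = 17))
  expect_false(identical(tab, generate_table(gen, 50, seed = 18)))
  expect_error(generate_table(gen, 0), "n must be")
})

test_that("generator gradients agree with finite differences", {
  tr <- manual_transformer(
    list(a = cont_meta(c(0, 4), c(1, 2), c(0.5, 0.5))),
    list(g = cat_meta(c("p", "q", "r"))),
    cat_freqs = list(g = c(0.3, 0.3, 0.4))
  )
  spec <- generator_spec(z_dim = 6, cont_widths = c(5), cat_width = 5, dropout = 0)
  gen <- build_generator(tr, spec, seed = 31)
  n <- 6
  cond <- sample_condition(tr, n, seed = 4)
  Z <- withr::with_seed(5, matrix(rnorm(n * 6), n, 6))
  # arbitrary fixed downstream gradient
  dRows <- withr::with_seed(6, matrix(rnorm(n * tr$width), n, tr$width))

  loss_of <- function(g) {
    sum(ehrsynth:::generator_forward(g, Z, cond, training = TRUE)$rows * dRows)
  }
  fw <- ehrsynth:::generator_forward(gen, Z, cond, training = TRUE)
  grads <- ehrsynth:::generator_backward(fw$gen, fw, dRows)

  h <- 1e-5
  dense_a <- which(vapply(gen$cont_nets$a, function(l) l$type == "dense", logical(1)))
  for (li in dense_a) {
    gp <- gen; gp$cont_nets$a[[li]]$W[1, 1] <- gp$cont_nets$a[[li]]$W[1, 1] + h
    gm <- gen; gm$cont_nets$a[[li]]$W[1, 1] <- gm$cont_nets$a[[li]]$W[1, 1] - h
    fd <- (loss_of(gp) - loss_of(gm)) / (2 * h)
    expect_equal(grads$a$net[[li]]$dW[1, 1], fd, tolerance = 1e-4)
  }
  # categorical pathway: a dense weight and an embedding entry
  gp <- gen; gp$cat_nets$g$net[[1]]$W[2, 2] <- gp$cat_nets$g$net[[1]]$W[2, 2] + h
  gm <- gen; gm$cat_nets$g$net[[1]]$W[2, 2] <- gm$cat_nets$g$net[[1]]$W[2, 2] - h
  expect_equal(grads$g$net[[1]]$dW[2, 2],
               (loss_of(gp) - loss_of(gm)) / (2 * h), tolerance = 1e-4)
  used <- cond$cat$g[1]
  gp <- gen; gp$cat_nets$g$emb[used, 1] <- gp$cat_nets$g$emb[used, 1] + h
  gm <- gen; gm$cat_nets$g$emb[used, 1] <- gm$cat_nets$g$emb[used, 1] - h
  expect_equal(grads$g$dEmb[used, 1],
               (loss_of(gp) - loss_of(gm)) / (2 * h), tolerance = 1e-4)
})
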