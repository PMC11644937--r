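test_that("minibatch discrimination matches its closed forms and the brute-force oracle", {
  kernel <- withr::with_seed(5, array(rnorm(4 * 3 * 2), dim = c(4, 3, 2)))

  # single row: no neighbours, similarities are empty sums
  one <- matrix(rnorm(4), 1)
  out <- minibatch_features(one, kernel)
  expect_equal(dim(out), c(1L, 4L + 3L))
  expect_equal(out[1, 5:7], c(0, 0, 0))

  # identical rows: each of (n - 1) neighbours contributes exp(0) = 1
  same <- matrix(1, 4, 4)
  out <- minibatch_features(same, kernel)
  expect_equal(unname(out[, 5:7]), matrix(3, 4, 3))

  # random batches against the double-loop oracle
  for (s in 1:20) {
    X <- withr::with_seed(s, matrix(rnorm(20), 5, 4))
    K <- withr::with_seed(s + 100, array(rnorm(4 * 3 * 2), dim = c(4, 3, 2)))
    expect_equal(minibatch_features(X, K), minibatch_oracle(X, K), tolerance = 1e-9)
  }

  expect_error(minibatch_features(matrix(1, 2, 3), kernel), "match batch width")
})

test_that("spectral normalization drives the top singular value to one", {
  expect_equal(spectral_normalize(diag(2))$W_hat, diag(2))
  expect_equal(spectral_normalize(2 * diag(2))$W_hat, diag(2))
  expect_equal(spectral_normalize(diag(c(3, 0)))$W_hat, diag(c(1, 0)))
  expect_error(spectral_normalize(matrix(0, 2, 2)), "all-zero")

  # power iteration vs full SVD oracle on random matrices
  for (s in 1:25) {
    W <- withr::with_seed(s, matrix(rnorm(35), 7, 5))
    sn <- spectral_normalize(W, steps = 5)
    expect_equal(sn$sigma, svd(W)$d[1], tolerance = 1e-3)
    expect_equal(svd(sn$W_hat)$d[1], 1, tolerance = 1e-3)
  }
})

test_that("the critic scores batches per its contracts", {
  spec <- critic_spec(widths = c(16, 8), mb_kernels = 4, mb_dim = 3)
  critic <- build_critic(10, spec, seed = 2)
  X <- withr::with_seed(3, matrix(rnorm(120), 12, 10))

  s <- critic_scores(critic, X)
  expect_length(s, 12)
  expect_true(all(is.finite(s)))

  # evaluation mode is deterministic: duplicated rows score identically
  dup <- rbind(X, X)
  sd2 <- critic_scores(critic, dup)
  expect_equal(sd2[1:12], sd2[13:24])

  # after a forward pass every spectrally wrapped layer has norm <= 1 + 1e-3
  fw <- ehrsynth:::critic_forward(critic, X, training = FALSE)
  for (ly in fw$critic$net) {
    if (!is.null(ly$sn) && isTRUE(ly$sn)) {
      sigma <- ehrsynth:::power_iteration(ly$W, ly$u, 300)$sigma
      expect_lte(svd(ly$W / sigma)$d[1], 1 + 1e-3)
    }
  }

  # permuting rows permutes scores identically
  perm <- withr::with_seed(9, sample.int(12))
  expect_equal(critic_scores(critic, X[perm, ]), s[perm], tolerance = 1e-10)

  expect_error(critic_scores(critic, X[, 1:9]), "input width")
})

test_that("critic gradients agree with finite differences", {
  spec <- critic_spec(widths = c(5, 4), mb_kernels = 2, mb_dim = 3,
                      dropout = 0, sn_steps_train = 50)
  critic <- build_critic(6, spec, seed = 4)
  X <- withr::with_seed(8, matrix(rnorm(30), 5, 6))

  loss_of <- function(cr) mean(ehrsynth:::critic_forward(cr, X, training = TRUE)$scores)

  fw <- ehrsynth:::critic_forward(critic, X, training = TRUE)
  critic <- fw$critic # warm, converged power-iteration state
  fw <- ehrsynth:::critic_forward(critic, X, training = TRUE)
  bw <- ehrsynth:::critic_backward(fw$critic, fw, rep(1 / 5, 5))

  h <- 1e-5
  # a few kernel entries
  for (idx in list(c(1, 1, 1), c(3, 2, 2), c(6, 1, 3))) {
    cp <- fw$critic; cp$kernel[idx[1], idx[2], idx[3]] <- cp$kernel[idx[1], idx[2], idx[3]] + h
    cm <- fw$critic; cm$kernel[idx[1], idx[2], idx[3]] <- cm$kernel[idx[1], idx[2], idx[3]] - h
    fd <- (loss_of(cp) - loss_of(cm)) / (2 * h)
    expect_equal(bw$dK[idx[1], idx[2], idx[3]], fd, tolerance = 1e-4)
  }
  # a few dense-weight entries across layers (including the final head)
  dense_layers <- which(vapply(fw$critic$net, function(l) l$type == "dense", logical(1)))
  for (li in dense_layers) {
    cp <- fw$critic; cp$net[[li]]$W[1, 1] <- cp$net[[li]]$W[1, 1] + h
    cm <- fw$critic; cm$net[[li]]$W[1, 1] <- cm$net[[li]]$W[1, 1] - h
    fd <- (loss_of(cp) - loss_of(cm)) / (2 * h)
    expect_equal(bw$grads[[li]]$dW[1, 1], fd, tolerance = 1e-3)
  }
})
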