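#' Adversarial loss components
#'
#' Scores follow the critic convention that higher values mean "more likely
#' synthetic". The Wasserstein critic loss is `mean(real) - mean(fake)`;
#' minimizing it widens the real/fake score separation. The generator loss is
#' `mean(fake)`: the generator pushes its samples toward "real" (low) scores.
#'
#' @param scores_real,scores_fake Non-empty numeric vectors of critic scores.
#' @return A single numeric loss value.
#' @export
critic_loss <- function(scores_real, scores_fake) {
  if (!length(scores_real) || !length(scores_fake)) stop("empty score list", call. = FALSE)
  mean(scores_real) - mean(scores_fake)
}

#' @rdname critic_loss
#' @export
generator_loss <- function(scores_fake) {
  if (!length(scores_fake)) stop("empty score list", call. = FALSE)
  mean(scores_fake)
}

#' Binary cross-entropy
#'
#' `-[y log(p) + (1 - y) log(1 - p)]` with probabilities clamped away from 0
#' and 1 by `eps` for numerical stability. Used by the reference
#' cross-entropy training mode.
#'
#' @param y Binary label(s), 0 or 1.
#' @param p Predicted probability(ies) of the positive class, in `[0, 1]`.
#' @param eps Clamp width (default 1e-7).
#' @return Elementwise loss value(s).
#' @export
bce_loss <- function(y, p, eps = 1e-7) {
  if (any(p < 0 | p > 1)) stop("p outside [0, 1]", call. = FALSE)
  if (any(!(y %in% c(0, 1)))) stop("y must be 0 or 1", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Training configuration
#'
#' @param epochs Number of passes over the data (default 300).
#' @param batch_size Minibatch size (default 32; must be >= 2 because minibatch
#'   discrimination needs more than one row).
#' @param lr Adam learning rate (default 2e-4).
#' @param betas Adam `(beta1, beta2)` (default `c(0.5, 0.9)`).
#' @param critic_steps Critic updates per generator update (default 1).
#' @param loss `"wasserstein"` (default) or `"bce"`. With `"bce"` the scalar
#'   critic output is passed through a logistic link; with `"wasserstein"` it
#'   is used raw, avoiding saturated gradients.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 300L, batch_size = 32L, lr = 2e-4,
                         betas = c(0.5, 0.9), critic_steps = 1L,
                         loss = c("wasserstein", "bce")) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1L, batch_size >= 2L, lr > 0, critic_steps >= 1L)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, betas = betas, critic_steps = as.integer(critic_steps),
                 loss = loss),
            class = "train_config")
}

# Score gradients for one batch under the chosen objective.
# Critic convention: higher score = synthetic. With BCE, p(real) = sigmoid(-score).
score_grads <- function(loss, s_real, s_fake) {
  nr <- length(s_real); nf <- length(s_fake)
  if (loss == "wasserstein") {
    list(l = critic_loss(s_real, s_fake),
         d_real = rep(1 / nr, nr), d_fake = rep(-1 / nf, nf))
  } else {
    q_real <- sigmoid(-s_real); q_fake <- sigmoid(-s_fake)
    l <- mean(bce_loss(1, q_real)) + mean(bce_loss(0, q_fake))
    # d BCE(y, sigmoid(-s)) / ds = y (1 - q) - (1 - y) q
    list(l = l, d_real = (1 - q_real) / nr, d_fake = -q_fake / nf)
  }
}

gen_score_grad <- function(loss, s_fake) {
  nf <- length(s_fake)
  if (loss == "wasserstein") {
    list(l = generator_loss(s_fake), d_fake = rep(1 / nf, nf))
  } else {
    q_fake <- sigmoid(-s_fake)
    list(l = mean(bce_loss(1, q_fake)), d_fake = (1 - q_fake) / nf)
  }
}

#' Fit the conditional GAN to a mixed-type table
#'
#' Fits the table transformer (mixture metadata + one-hot vocabularies), then
#' alternates Adam updates of the critic and the conditional generator under
#' the Wasserstein objective (or binary cross-entropy in the reference mode).
#' Conditions are re-sampled fresh every batch; real rows are visited in a
#' random order without replacement each epoch. All randomness — transform
#' fit, weight initialisation, batching, noise, conditions, dropout — derives
#' from the single `seed`, so identical calls are bit-identical.
#'
#' @param data A data frame of real records conforming to `schema`.
#' @param schema A [table_schema()].
#' @param config A [train_config()].
#' @param gen_spec A [generator_spec()].
#' @param crit_spec A [critic_spec()].
#' @param max_modes Maximum mixture components per continuous column.
#' @param seed Master integer seed (default 1).
#' @param missing Passed to [check_table()].
#' @param verbose Print per-epoch losses?
#' @return An `ehrgan` fit: list with `generator`, `critic`, `transformer`,
#'   `history` (per-epoch tibble) and `config`. Use [generate_table()] on
#'   `$generator`, or [sample_synthetic()] on the fit.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n = 80, seed = 7)
#' fit <- ehrgan_fit(cohort, cohort_schema(), train_config(epochs = 2), seed = 1)
#' synth <- sample_synthetic(fit, n = 50, seed = 2)
#' }
ehrgan_fit <- function(data, schema, config = train_config(),
                       gen_spec = generator_spec(), crit_spec = critic_spec(),
                       max_modes = 10L, seed = 1L,
                       missing = c("error", "drop_rows"), verbose = FALSE) {
  missing <- match.arg(missing)
  set.seed(as.integer(seed))
  data <- check_table(data, schema, missing = missing)
  n <- nrow(data)
  if (config$batch_size > n) stop("batch size exceeds number of rows", call. = FALSE)

  transformer <- fit_transformer(data, schema, max_modes = max_modes, seed = seed)
  real <- transform_table(transformer, data)$values
  gen <- build_generator(transformer, gen_spec)
  critic <- build_critic(transformer$width, crit_spec)
  opt <- list(lr = config$lr, beta1 = config$betas[1L], beta2 = config$betas[2L],
              eps = 1e-8)

  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    order <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ld <- lg <- sr <- sf <- c()
    for (s in starts) {
      idx <- order[s:min(s + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next # minibatch discrimination needs > 1 row
      bs <- length(idx)

      for (cs in seq_len(config$critic_steps)) {
        cond <- sample_condition(transformer, bs)
        Z <- matrix(stats::rnorm(bs * gen$spec$z_dim), bs)
        gfw <- generator_forward(gen, Z, cond, training = TRUE)
        gen <- gfw$gen
        fr <- critic_forward(critic, real[idx, , drop = FALSE], training = TRUE)
        critic <- fr$critic
        ff <- critic_forward(critic, gfw$rows, training = TRUE)
        critic <- ff$critic
        sg <- score_grads(config$loss, fr$scores, ff$scores)
        if (!is.finite(sg$l)) stop("non-finite critic loss at epoch ", epoch, call. = FALSE)
        br <- critic_backward(critic, fr, sg$d_real)
        bf <- critic_backward(critic, ff, sg$d_fake)
        grads <- merge_grads(br$grads, bf$grads)
        critic <- critic_step(critic, grads, br$dK + bf$dK, opt)
        ld <- c(ld, sg$l)
        sr <- c(sr, mean(fr$scores)); sf <- c(sf, mean(ff$scores))
      }

      cond <- sample_condition(transformer, bs)
      Z <- matrix(stats::rnorm(bs * gen$spec$z_dim), bs)
      gfw <- generator_forward(gen, Z, cond, training = TRUE)
      gen <- gfw$gen
      ff <- critic_forward(critic, gfw$rows, training = TRUE)
      critic <- ff$critic
      gg <- gen_score_grad(config$loss, ff$scores)
      if (!is.finite(gg$l)) stop("non-finite generator loss at epoch ", epoch, call. = FALSE)
      bf <- critic_backward(critic, ff, gg$d_fake)
      ggrads <- generator_backward(gen, gfw, bf$dX)
      gen <- generator_step(gen, ggrads, opt)
      lg <- c(lg, gg$l)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, critic_loss = mean(ld), generator_loss = mean(lg),
      mean_score_real = mean(sr), mean_score_fake = mean(sf)
    )
    if (verbose) {
      message(sprintf("epoch %d: l_D = %.4f, l_G = %.4f", epoch, mean(ld), mean(lg)))
    }
  }

  structure(list(generator = gen, critic = critic, transformer = transformer,
                 history = dplyr::bind_rows(history), config = config,
                 seed = as.integer(seed), n = n),
            class = "ehrgan")
}

merge_grads <- function(a, b) {
  lapply(seq_along(a), function(i) {
    if (is.null(a[[i]])) return(NULL)
    Map(`+`, a[[i]], b[[i]])
  })
}

#' Sample synthetic rows from a fitted model
#'
#' @param fit An [ehrgan_fit()] result.
#' @param n Number of rows (defaults to the training-set size).
#' @param seed Optional integer seed.
#' @param categorical `"sample"` or `"argmax"` categorical decoding.
#' @return A tibble of `n` synthetic records.
#' @export
sample_synthetic <- function(fit, n = fit$n, seed = NULL,
                             categorical = c("sample", "argmax")) {
  stopifnot(inherits(fit, "ehrgan"))
  generate_table(fit$generator, n, seed = seed, categorical = categorical)
}

#' @export
print.ehrgan <- function(x, ...) {
  cat("<ehrgan> trained ", nrow(x$history), " epochs on ", x$n, " rows (",
      x$config$loss, " loss)\n", sep = "")
  cat("final critic loss ", round(utils::tail(x$history$critic_loss, 1L), 4L),
      ", generator loss ", round(utils::tail(x$history$generator_loss, 1L), 4L),
      "\n", sep = "")
  invisible(x)
}

#' Save / load a fitted model archive
#'
#' The archive bundles the generator, critic, transformer metadata and history
#' in a single file so `sample` runs from disk.
#'
#' @param fit An `ehrgan` fit.
#' @param path File path.
#' @return `read_ehrgan()` returns the restored fit; `write_ehrgan()` returns
#'   `path` invisibly.
#' @export
write_ehrgan <- function(fit, path) {
  stopifnot(inherits(fit, "ehrgan"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_ehrgan
#' @export
read_ehrgan <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "ehrgan")) stop("not an ehrgan archive", call. = FALSE)
  fit
}
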