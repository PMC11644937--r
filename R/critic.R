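#' Critic architecture settings
#'
#' @param widths Hidden dense-layer widths (default `c(256, 128)`).
#' @param mb_kernels Number of minibatch-discrimination kernels `B` (default 16).
#' @param mb_dim Kernel projection dimension `C` (default 8).
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @param dropout Dropout rate (default 0.3).
#' @param sn_steps_train,sn_steps_eval Power iterations per forward pass during
#'   training (default 1) and evaluation (default 5).
#' @param batchnorm Keep batch normalization inside the spectrally normalized
#'   critic (default `TRUE`); set `FALSE` for a stricter Lipschitz surrogate.
#' @return A `critic_spec` list.
#' @export
critic_spec <- function(widths = c(256L, 128L), mb_kernels = 16L, mb_dim = 8L,
                        leaky_slope = 0.2, dropout = 0.3,
                        sn_steps_train = 1L, sn_steps_eval = 5L, batchnorm = TRUE) {
  stopifnot(mb_kernels >= 1L, mb_dim >= 1L, all(widths >= 1L), dropout < 1)
  structure(list(widths = as.integer(widths), mb_kernels = as.integer(mb_kernels),
                 mb_dim = as.integer(mb_dim), leaky_slope = leaky_slope,
                 dropout = dropout, sn_steps_train = as.integer(sn_steps_train),
                 sn_steps_eval = as.integer(sn_steps_eval), batchnorm = batchnorm),
            class = "critic_spec")
}

#' Minibatch discrimination features
#'
#' Projects each row through `B` kernels of dimension `C` and appends, per row
#' and kernel, the summed negative-exponential L1 distance to every other row
#' in the batch: `o_i[b] = sum_{j != i} exp(-||M_i,b - M_j,b||_1)`. A collapsed
#' (low-diversity) batch yields large similarity statistics, which the critic
#' learns to flag as synthetic.
#'
#' @param batch Numeric matrix, `n x d`.
#' @param kernel Numeric array `d x B x C` (or a `d x (B*C)` matrix).
#' @return `n x (d + B)` matrix: the input with `B` similarity columns appended.
#' @export
minibatch_features <- function(batch, kernel) {
  mb_forward(as.matrix(batch), kernel)$out
}

mb_forward <- function(X, kernel) {
  d <- ncol(X)
  if (!(is.array(kernel) && length(dim(kernel)) == 3L)) {
    stop("kernel must be a d x B x C array", call. = FALSE)
  }
  if (dim(kernel)[1L] != d) stop("kernel first dimension must match batch width", call. = FALSE)
  B <- dim(kernel)[2L]; C <- dim(kernel)[3L]
  # flatten to d x (B*C) with the C columns of each kernel contiguous
  K <- matrix(aperm(kernel, c(1L, 3L, 2L)), d, B * C)
  n <- nrow(X)
  M <- X %*% K
  O <- matrix(0, n, B)
  A <- vector("list", B)
  if (n > 1L) {
    for (b in seq_len(B)) {
      Mb <- M[, (b - 1L) * C + seq_len(C), drop = FALSE]
      Ab <- exp(-as.matrix(stats::dist(Mb, method = "manhattan")))
      diag(Ab) <- 0
      A[[b]] <- Ab
      O[, b] <- rowSums(Ab)
    }
  }
  list(out = cbind(X, O), cache = list(X = X, M = M, A = A, B = B, C = C, d = d))
}

#' Spectral normalization of a weight matrix
#'
#' Estimates the largest singular value of `W` by power iteration (warm-started
#' from a persistent vector `u`) and returns `W` divided by it, bounding the
#' layer's Lipschitz constant near 1.
#'
#' @param W A non-zero numeric matrix.
#' @param u Optional persistent left power-iteration vector (length `nrow(W)`).
#' @param steps Number of power iterations (default 1; use more when `u` is cold).
#' @return List with `W_hat` (normalized matrix), `u` (updated state) and
#'   `sigma` (the spectral-norm estimate).
#' @export
spectral_normalize <- function(W, u = NULL, steps = 1L) {
  W <- as.matrix(W)
  if (all(W == 0)) stop("all-zero weight matrix", call. = FALSE)
  if (is.null(u)) {
    # cold start: iterate to convergence of the singular-value estimate
    u <- 1 + 1e-3 * seq_len(nrow(W)) # deterministic, generic start
    u <- u / sqrt(sum(u^2))
    sigma <- 0
    for (i in seq_len(1000L)) {
      pi <- power_iteration(W, u, steps)
      u <- pi$u
      if (abs(pi$sigma - sigma) < 1e-9 * max(pi$sigma, 1e-12)) break
      sigma <- pi$sigma
    }
  } else {
    pi <- power_iteration(W, u, steps)
  }
  list(W_hat = W / pi$sigma, u = pi$u, sigma = pi$sigma)
}

#' Build the critic network
#'
#' The critic scores each row of a batch in the flat transformed layout:
#' minibatch-discrimination features first, then spectrally normalized dense
#' layers with LeakyReLU, batch normalization and dropout, ending in a
#' spectrally normalized linear unit with no activation. Higher scores mean
#' "more likely synthetic".
#'
#' @param input_width Width of the flat transformed row the critic consumes.
#' @param spec A [critic_spec()].
#' @param seed Optional integer seed for weight initialisation.
#' @return A `tab_critic` handle; score batches with [critic_scores()].
#' @export
build_critic <- function(input_width, spec = critic_spec(), seed = NULL) {
  build <- function() {
    d <- as.integer(input_width)
    B <- spec$mb_kernels; C <- spec$mb_dim
    kernel <- array(stats::rnorm(d * B * C, sd = sqrt(1 / d)), dim = c(d, B, C))
    layers <- list()
    w_in <- d + B
    for (w in spec$widths) {
      layers <- c(layers, list(layer_dense(w_in, w, sn = TRUE),
                               layer_act("leaky", spec$leaky_slope)))
      if (spec$batchnorm) layers <- c(layers, list(layer_bn(w)))
      layers <- c(layers, list(layer_dropout(spec$dropout)))
      w_in <- w
    }
    layers <- c(layers, list(layer_dense(w_in, 1L, sn = TRUE)))
    structure(list(kernel = kernel, aK = adam_state(kernel), net = layers,
                   spec = spec, input_width = d),
              class = "tab_critic")
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' Score a batch with the critic
#'
#' @param critic A [build_critic()] handle.
#' @param batch Numeric matrix (`n x input_width`) in the transformed layout.
#' @param training Use training-mode stochastic layers (dropout, batch
#'   statistics)? Default `FALSE` (deterministic evaluation).
#' @return Numeric vector of `n` unbounded scores (higher = more likely synthetic).
#' @export
critic_scores <- function(critic, batch, training = FALSE) {
  critic_forward(critic, as.matrix(batch), training = training)$scores
}

critic_forward <- function(critic, X, training = TRUE) {
  if (ncol(X) != critic$input_width) {
    stop("batch width ", ncol(X), " does not match critic input width ",
         critic$input_width, call. = FALSE)
  }
  mb <- mb_forward(X, critic$kernel)
  steps <- if (training) critic$spec$sn_steps_train else critic$spec$sn_steps_eval
  fw <- net_forward(critic$net, mb$out, training = training, sn_steps = steps)
  critic$net <- fw$net
  list(critic = critic, scores = drop(fw$out), mb_cache = mb$cache, caches = fw$caches)
}

critic_backward <- function(critic, fwd, dscores) {
  dOut <- matrix(dscores, ncol = 1L)
  bw <- net_backward(critic$net, fwd$caches, dOut)
  ca <- fwd$mb_cache
  d <- ca$d; B <- ca$B; C <- ca$C; n <- nrow(ca$X)
  dMB <- bw$dX # n x (d + B)
  dX <- dMB[, seq_len(d), drop = FALSE]
  dK <- matrix(0, d, B * C)
  if (n > 1L) {
    K <- matrix(aperm(critic$kernel, c(1L, 3L, 2L)), d, B * C)
    dM <- matrix(0, n, B * C)
    for (b in seq_len(B)) {
      g <- dMB[, d + b]
      coef <- -(outer(g, rep(1, n)) + outer(rep(1, n), g)) * ca$A[[b]]
      idx <- (b - 1L) * C + seq_len(C)
      Mb <- ca$M[, idx, drop = FALSE]
      for (cc in seq_len(C)) {
        S <- sign(outer(Mb[, cc], Mb[, cc], "-"))
        dM[, idx[cc]] <- rowSums(coef * S)
      }
    }
    dX <- dX + tcrossprod(dM, K)
    dK <- crossprod(ca$X, dM)
  }
  # undo the (c fast, b slow) flattening back to d x B x C
  list(dX = dX, grads = bw$grads,
       dK = aperm(array(dK, dim = c(d, C, B)), c(1L, 3L, 2L)))
}

critic_step <- function(critic, grads, dK, opt) {
  up <- adam_update(critic$kernel, dK, critic$aK, opt)
  critic$kernel <- up$param; critic$aK <- up$state
  critic$net <- net_adam(critic$net, grads, opt)
  critic
}

#' @export
print.tab_critic <- function(x, ...) {
  cat("<tab_critic> input width ", x$input_width, ", dense widths [",
      paste(x$spec$widths, collapse = ", "), "], ", x$spec$mb_kernels,
      " minibatch kernels\n", sep = "")
  invisible(x)
}
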