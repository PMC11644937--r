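# Minimal dense-network machinery with explicit reverse-mode gradients.
# Conventions: activations are n x d matrices (rows = samples); a dense layer
# stores W (in x out) and bias b; all parameter initialisation draws from the
# session RNG so a single master seed makes whole training runs reproducible.

rowvec_add <- function(Y, b) Y + rep(b, each = nrow(Y))
rowvec_mul <- function(Y, g) Y * rep(g, each = nrow(Y))

adam_update <- function(param, grad, state, opt) {
  state$t <- state$t + 1L
  state$m <- opt$beta1 * state$m + (1 - opt$beta1) * grad
  state$v <- opt$beta2 * state$v + (1 - opt$beta2) * grad^2
  mhat <- state$m / (1 - opt$beta1^state$t)
  vhat <- state$v / (1 - opt$beta2^state$t)
  list(param = param - opt$lr * mhat / (sqrt(vhat) + opt$eps), state = state)
}

adam_state <- function(param) list(m = param * 0, v = param * 0, t = 0L)

layer_dense <- function(n_in, n_out, sn = FALSE) {
  W <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  b <- numeric(n_out)
  u <- stats::rnorm(n_in)
  list(type = "dense", W = W, b = b, sn = sn, u = u / sqrt(sum(u^2)),
       aW = adam_state(W), ab = adam_state(b))
}

layer_bn <- function(d) {
  list(type = "bn", gamma = rep(1, d), beta = numeric(d),
       run_mean = numeric(d), run_var = rep(1, d), momentum = 0.9, eps = 1e-5,
       ag = adam_state(numeric(d)), ab = adam_state(numeric(d)))
}

layer_act <- function(fun, slope = 0.2) list(type = "act", fun = fun, slope = slope)
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_softmax <- function() list(type = "softmax")

# Power-iteration estimate of the largest singular value of W, warm-started
# from the persistent left vector u.
power_iteration <- function(W, u, steps) {
  for (s in seq_len(steps)) {
    v <- drop(crossprod(W, u))
    v <- v / max(sqrt(sum(v^2)), 1e-12)
    u <- drop(W %*% v)
    u <- u / max(sqrt(sum(u^2)), 1e-12)
  }
  list(sigma = max(drop(crossprod(u, W %*% v)), 1e-12), u = u, v = v)
}

net_forward <- function(net, X, training = TRUE, sn_steps = 1L) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    ly <- net[[i]]
    switch(ly$type,
      dense = {
        if (ly$sn) {
          pi <- power_iteration(ly$W, ly$u, sn_steps)
          net[[i]]$u <- pi$u
          What <- ly$W / pi$sigma
          caches[[i]] <- list(X = X, What = What, sigma = pi$sigma, u = pi$u, v = pi$v)
        } else {
          What <- ly$W
          caches[[i]] <- list(X = X, What = What)
        }
        X <- rowvec_add(X %*% What, ly$b)
      },
      bn = {
        if (training) {
          mu <- colMeans(X)
          Xc <- rowvec_add(X, -mu)
          va <- colMeans(Xc^2)
          inv_std <- 1 / sqrt(va + ly$eps)
          xhat <- rowvec_mul(Xc, inv_std)
          net[[i]]$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
          net[[i]]$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * va
        } else {
          inv_std <- 1 / sqrt(ly$run_var + ly$eps)
          xhat <- rowvec_mul(rowvec_add(X, -ly$run_mean), inv_std)
        }
        caches[[i]] <- list(xhat = xhat, inv_std = inv_std, training = training)
        X <- rowvec_add(rowvec_mul(xhat, ly$gamma), ly$beta)
      },
      act = {
        if (ly$fun == "leaky") {
          neg <- X < 0
          caches[[i]] <- list(neg = neg)
          X <- ifelse(neg, ly$slope * X, X)
        } else if (ly$fun == "relu") {
          neg <- X < 0
          caches[[i]] <- list(neg = neg)
          X[neg] <- 0
        } else if (ly$fun == "tanh99") {
          Th <- tanh(X)
          caches[[i]] <- list(Th = Th)
          X <- 0.99 * Th
        }
      },
      dropout = {
        if (training && ly$rate > 0) {
          mask <- (matrix(stats::runif(length(X)), nrow(X)) >= ly$rate) / (1 - ly$rate)
          caches[[i]] <- list(mask = mask)
          X <- X * mask
        }
      },
      softmax = {
        P <- exp(X - apply(X, 1L, max))
        P <- P / rowSums(P)
        caches[[i]] <- list(P = P)
        X <- P
      }
    )
  }
  list(net = net, out = X, caches = caches)
}

net_backward <- function(net, caches, dOut) {
  grads <- vector("list", length(net))
  dX <- dOut
  for (i in rev(seq_along(net))) {
    ly <- net[[i]]
    ca <- caches[[i]]
    switch(ly$type,
      dense = {
        db <- colSums(dX)
        G <- crossprod(ca$X, dX) # gradient w.r.t. the (normalized) weight
        dXnew <- tcrossprod(dX, ca$What)
        dW <- if (ly$sn) {
          G / ca$sigma - (sum(G * ly$W) / ca$sigma^2) * tcrossprod(ca$u, ca$v)
        } else G
        grads[[i]] <- list(dW = dW, db = db)
        dX <- dXnew
      },
      bn = {
        stopifnot(ca$training)
        dgamma <- colSums(dX * ca$xhat)
        dbeta <- colSums(dX)
        dxhat <- rowvec_mul(dX, ly$gamma)
        n <- nrow(dX)
        dX <- rowvec_mul(
          dxhat - rowvec_add(ca$xhat * 0, colMeans(dxhat)) -
            rowvec_mul(ca$xhat, colMeans(dxhat * ca$xhat)),
          ca$inv_std
        )
        grads[[i]] <- list(dgamma = dgamma, dbeta = dbeta)
      },
      act = {
        if (ly$fun == "leaky") {
          dX <- ifelse(ca$neg, ly$slope * dX, dX)
        } else if (ly$fun == "relu") {
          dX[ca$neg] <- 0
        } else if (ly$fun == "tanh99") {
          dX <- dX * 0.99 * (1 - ca$Th^2)
        }
      },
      dropout = {
        if (!is.null(ca$mask)) dX <- dX * ca$mask
      },
      softmax = {
        dX <- (dX - rowSums(dX * ca$P)) * ca$P
      }
    )
  }
  list(dX = dX, grads = grads)
}

net_adam <- function(net, grads, opt) {
  for (i in seq_along(net)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ly <- net[[i]]
    if (ly$type == "dense") {
      up <- adam_update(ly$W, g$dW, ly$aW, opt)
      net[[i]]$W <- up$param; net[[i]]$aW <- up$state
      up <- adam_update(ly$b, g$db, ly$ab, opt)
      net[[i]]$b <- up$param; net[[i]]$ab <- up$state
    } else if (ly$type == "bn") {
      up <- adam_update(ly$gamma, g$dgamma, ly$ag, opt)
      net[[i]]$gamma <- up$param; net[[i]]$ag <- up$state
      up <- adam_update(ly$beta, g$dbeta, ly$ab, opt)
      net[[i]]$beta <- up$param; net[[i]]$ab <- up$state
    }
  }
  net
}

# Flatten all trainable parameters of a net into one numeric vector (used by
# tests to verify optimizer isolation).
net_params <- function(net) {
  unlist(lapply(net, function(ly) {
    if (ly$type == "dense") c(ly$W, ly$b)
    else if (ly$type == "bn") c(ly$gamma, ly$beta)
    else numeric(0)
  }))
}
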