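#' Generator architecture settings
#'
#' @param z_dim Total noise dimension, sliced across the per-column pathways
#'   (default 128).
#' @param cont_widths Hidden widths of each continuous sub-network (default `c(64, 64)`).
#' @param cat_width Hidden width of each categorical sub-network (default 64).
#' @param leaky_slope LeakyReLU negative slope in continuous pathways (default 0.2).
#' @param dropout Dropout rate (default 0.2).
#' @param embed_max Embedding dimension is `min(embed_max, n_classes)` (default 8).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(z_dim = 128L, cont_widths = c(64L, 64L), cat_width = 64L,
                           leaky_slope = 0.2, dropout = 0.2, embed_max = 8L) {
  stopifnot(z_dim >= 1L, dropout < 1, all(cont_widths >= 1L), cat_width >= 1L)
  structure(list(z_dim = as.integer(z_dim), cont_widths = as.integer(cont_widths),
                 cat_width = as.integer(cat_width), leaky_slope = leaky_slope,
                 dropout = dropout, embed_max = as.integer(embed_max)),
            class = "generator_spec")
}

#' Sample condition vectors
#'
#' For each continuous column a mixture mode is drawn from the fitted component
#' weights; for each categorical column a class is drawn from its empirical
#' frequency. The condition steers the corresponding generator pathway and is
#' copied verbatim into the output layout, so inversion is well defined.
#'
#' @param transformer A [fit_transformer()] result.
#' @param n Number of condition rows to draw.
#' @param frequencies Optional named list of per-categorical-column probability
#'   vectors (defaults to the empirical frequencies stored in the transformer).
#' @param seed Optional integer seed.
#' @return A `condition_set`: list with `cont` (named list of mode indices) and
#'   `cat` (named list of class indices), all 1-based integer vectors of length `n`.
#' @export
sample_condition <- function(transformer, n = 1L, frequencies = NULL, seed = NULL) {
  draw <- function() {
    freqs <- frequencies %||% transformer$cat_freqs
    sch <- transformer$schema
    cont <- list(); cat <- list()
    for (i in seq_len(nrow(sch))) {
      col <- sch$column[i]
      meta <- transformer$metas[[col]]
      if (sch$kind[i] == "continuous") {
        cont[[col]] <- sample.int(meta$n_modes, n, replace = TRUE, prob = meta$weights)
      } else {
        p <- freqs[[col]]
        if (is.null(p)) p <- rep(1 / meta$n_classes, meta$n_classes)
        if (length(p) != meta$n_classes) {
          stop("frequency/vocabulary length mismatch for ", col, call. = FALSE)
        }
        cat[[col]] <- sample.int(meta$n_classes, n, replace = TRUE, prob = p)
      }
    }
    structure(list(cont = cont, cat = cat, n = n), class = "condition_set")
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contiguous noise-slice indices per pathway (schema order, continuous then
# categorical interleaved as declared).
z_slices <- function(schema, z_dim) {
  n_path <- nrow(schema)
  width <- max(1L, z_dim %/% n_path)
  stats::setNames(lapply(seq_len(n_path), function(i) {
    ((i - 1L) * width + 1L):(i * width)
  }), schema$column)
}

#' Build the conditional generator
#'
#' Continuous and categorical variables are produced by separate pathways. Each
#' continuous column has its own sub-network taking `[z-slice, one-hot mode,
#' standardized (mu_k, sigma_k)]` through dense / LeakyReLU / batch-norm /
#' dropout stacks into a `0.99 * tanh` head, so outputs respect the clip range
#' by construction. Each categorical column embeds the conditioned class,
#' concatenates its z-slice, and maps through a ReLU dense stack into a
#' per-column softmax. Pathway outputs are concatenated into the flat
#' transformed-row layout (the conditioned mode one-hots are copied through).
#'
#' @param transformer A [fit_transformer()] result.
#' @param spec A [generator_spec()].
#' @param seed Optional integer seed for weight initialisation.
#' @return A `tab_generator` handle for [generate_table()].
#' @export
build_generator <- function(transformer, spec = generator_spec(), seed = NULL) {
  build <- function() {
    sch <- transformer$schema
    slices <- z_slices(sch, spec$z_dim)
    cont_nets <- list(); cont_info <- list(); cat_nets <- list()
    for (i in seq_len(nrow(sch))) {
      col <- sch$column[i]
      meta <- transformer$metas[[col]]
      zw <- length(slices[[col]])
      if (sch$kind[i] == "continuous") {
        s <- max(meta$sd, 1e-12)
        cont_info[[col]] <- list(mu_std = (meta$means - meta$mean) / s,
                                 sd_std = meta$stds / s)
        layers <- list()
        w_in <- zw + meta$n_modes + 2L
        for (w in spec$cont_widths) {
          layers <- c(layers, list(layer_dense(w_in, w),
                                   layer_act("leaky", spec$leaky_slope),
                                   layer_bn(w), layer_dropout(spec$dropout)))
          w_in <- w
        }
        layers <- c(layers, list(layer_dense(w_in, 1L), layer_act("tanh99")))
        cont_nets[[col]] <- layers
      } else {
        e <- min(spec$embed_max, meta$n_classes)
        emb <- matrix(stats::rnorm(meta$n_classes * e, sd = 0.1), meta$n_classes, e)
        layers <- list(layer_dense(zw + e, spec$cat_width), layer_act("relu"),
                       layer_bn(spec$cat_width), layer_dropout(spec$dropout),
                       layer_dense(spec$cat_width, meta$n_classes), layer_softmax())
        cat_nets[[col]] <- list(emb = emb, aE = adam_state(emb), net = layers)
      }
    }
    structure(list(transformer = transformer, spec = spec, slices = slices,
                   cont_nets = cont_nets, cont_info = cont_info,
                   cat_nets = cat_nets, width = transformer$width),
              class = "tab_generator")
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' @export
print.tab_generator <- function(x, ...) {
  cat("<tab_generator> ", length(x$cont_nets), " continuous + ",
      length(x$cat_nets), " categorical pathways, z_dim ", x$spec$z_dim,
      ", output width ", x$width, "\n", sep = "")
  invisible(x)
}

generator_forward <- function(gen, Z, cond, training = TRUE) {
  tr <- gen$transformer
  lay <- tr$layout
  n <- nrow(Z)
  rows <- matrix(0, n, tr$width)
  fwds <- list()
  for (i in seq_len(nrow(lay))) {
    col <- lay$column[i]
    meta <- tr$metas[[col]]
    at <- lay$start[i]
    Zs <- Z[, gen$slices[[col]], drop = FALSE]
    if (lay$kind[i] == "continuous") {
      k <- cond$cont[[col]]
      onehot <- matrix(0, n, meta$n_modes)
      onehot[cbind(seq_len(n), k)] <- 1
      info <- gen$cont_info[[col]]
      U <- cbind(Zs, onehot, info$mu_std[k], info$sd_std[k])
      fw <- net_forward(gen$cont_nets[[col]], U, training = training)
      gen$cont_nets[[col]] <- fw$net
      fwds[[col]] <- fw
      rows[, at] <- drop(fw$out)
      rows[, at + seq_len(meta$n_modes)] <- onehot # condition passed through
    } else {
      idx <- cond$cat[[col]]
      cn <- gen$cat_nets[[col]]
      U <- cbind(Zs, cn$emb[idx, , drop = FALSE])
      fw <- net_forward(cn$net, U, training = training)
      gen$cat_nets[[col]]$net <- fw$net
      fw$idx <- idx
      fwds[[col]] <- fw
      rows[, at + seq_len(meta$n_classes) - 1L] <- fw$out
    }
  }
  list(gen = gen, rows = rows, fwds = fwds)
}

generator_backward <- function(gen, fwd, dRows) {
  lay <- gen$transformer$layout
  grads <- list()
  for (i in seq_len(nrow(lay))) {
    col <- lay$column[i]
    meta <- gen$transformer$metas[[col]]
    at <- lay$start[i]
    fw <- fwd$fwds[[col]]
    if (lay$kind[i] == "continuous") {
      dOut <- matrix(dRows[, at], ncol = 1L)
      bw <- net_backward(gen$cont_nets[[col]], fw$caches, dOut)
      grads[[col]] <- list(net = bw$grads)
    } else {
      dOut <- dRows[, at + seq_len(meta$n_classes) - 1L, drop = FALSE]
      bw <- net_backward(gen$cat_nets[[col]]$net, fw$caches, dOut)
      zw <- length(gen$slices[[col]])
      dE_rows <- bw$dX[, -seq_len(zw), drop = FALSE]
      dEmb <- gen$cat_nets[[col]]$emb * 0
      agg <- rowsum(dE_rows, group = fw$idx)
      dEmb[as.integer(rownames(agg)), ] <- agg
      grads[[col]] <- list(net = bw$grads, dEmb = dEmb)
    }
  }
  grads
}

generator_step <- function(gen, grads, opt) {
  for (col in names(gen$cont_nets)) {
    gen$cont_nets[[col]] <- net_adam(gen$cont_nets[[col]], grads[[col]]$net, opt)
  }
  for (col in names(gen$cat_nets)) {
    cn <- gen$cat_nets[[col]]
    cn$net <- net_adam(cn$net, grads[[col]]$net, opt)
    up <- adam_update(cn$emb, grads[[col]]$dEmb, cn$aE, opt)
    cn$emb <- up$param; cn$aE <- up$state
    gen$cat_nets[[col]] <- cn
  }
  gen
}

generator_params <- function(gen) {
  c(unlist(lapply(gen$cont_nets, net_params)),
    unlist(lapply(gen$cat_nets, function(cn) c(cn$emb, net_params(cn$net)))))
}

#' Generate a synthetic table
#'
#' Draws `n` (noise, condition) pairs, runs the generator in evaluation mode,
#' and inverse-transforms the result: continuous cells are denormalized with
#' their conditioned mixture mode, categorical softmax blocks are decoded by
#' proportional sampling (default) or argmax.
#'
#' @param generator A [build_generator()] handle (trained or untrained).
#' @param n Number of rows to generate (>= 1).
#' @param seed Optional integer seed; identical seeds give identical tables.
#' @param categorical `"sample"` (default) or `"argmax"` decoding.
#' @return A tibble of `n` rows conforming to the training schema.
#' @export
generate_table <- function(generator, n, seed = NULL,
                           categorical = c("sample", "argmax")) {
  categorical <- match.arg(categorical)
  if (length(n) != 1L || !is.finite(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  run <- function() {
    cond <- sample_condition(generator$transformer, n)
    Z <- matrix(stats::rnorm(n * generator$spec$z_dim), n, generator$spec$z_dim)
    fw <- generator_forward(generator, Z, cond, training = FALSE)
    inverse_transform_table(generator$transformer, fw$rows, categorical = categorical)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}
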