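#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted model
#'
#' @param x An [ehrgan_fit()] result.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `critic_loss`,
#'   `generator_loss`, `mean_score_real`, `mean_score_fake`.
#' @export
tidy.ehrgan <- function(x, ...) x$history

#' @rdname tidy.ehrgan
#' @return `glance()`: a one-row tibble summarising the fit.
#' @export
glance.ehrgan <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    n = x$n,
    loss = x$config$loss,
    batch_size = x$config$batch_size,
    final_critic_loss = utils::tail(x$history$critic_loss, 1L),
    final_generator_loss = utils::tail(x$history$generator_loss, 1L),
    seed = x$seed
  )
}

#' Tidy a fidelity report
#'
#' @param x An [evaluate_fidelity()] result.
#' @param ... Unused.
#' @return A tibble with one row per column: `column`, `kind`, `metric`
#'   (`"ks"` or `"jaccard"`) and `value`.
#' @export
tidy.fidelity_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$continuous, kind = "continuous", metric = "ks",
                  value = .data$ks, ks = NULL),
    dplyr::mutate(x$categorical, kind = "categorical", metric = "jaccard",
                  value = .data$jaccard, jaccard = NULL)
  )[, c("column", "kind", "metric", "value")]
}

#' @rdname tidy.fidelity_report
#' @return `glance()`: a one-row tibble with `mean_ks`, `preservation_rate`,
#'   `tau` and the column counts.
#' @export
glance.fidelity_report <- function(x, ...) {
  tibble::tibble(
    mean_ks = x$mean_ks,
    preservation_rate = x$preservation_rate,
    tau = x$tau,
    n_continuous = nrow(x$continuous),
    n_categorical = nrow(x$categorical),
    n_real = x$n_real,
    n_synth = x$n_synth
  )
}

#' Plot per-column fidelity metrics
#'
#' Bar chart of per-column KS statistics (lower is better) and Jaccard
#' similarities (higher is better), faceted by metric.
#'
#' @param object An [evaluate_fidelity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$column, .data$value),
                                   y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Synthetic-data fidelity by column",
                  subtitle = "ks: lower is better; jaccard: 1 = category sets match") +
    ggplot2::theme_minimal()
}

#' Plot adversarial training curves
#'
#' @param object An [ehrgan_fit()] result.
#' @param ... Unused.
#' @return A ggplot object with critic and generator loss per epoch.
#' @export
autoplot.ehrgan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            cols = c("critic_loss", "generator_loss"),
                            names_to = "network", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$network)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Adversarial training history", y = "loss") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
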