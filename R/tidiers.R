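#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `sirna_sage` model.
#' @param ... Unused.
#' @return Tibble: `epoch, train_mse, val_mse, val_pcc`.
#' @method tidy sirna_sage
#' @export
tidy.sirna_sage <- function(x, ...) {
  x$history
}

#' One-row model summary
#'
#' @param x A `sirna_sage` model.
#' @param ... Unused.
#' @return Tibble: `epochs, best_epoch, val_pcc, val_mse, n_parameters`.
#' @method glance sirna_sage
#' @export
glance.sirna_sage <- function(x, ...) {
  h <- x$history[x$history$epoch == x$best_epoch, ]
  tibble(
    epochs = x$config$epochs,
    best_epoch = x$best_epoch,
    val_pcc = if (nrow(h)) h$val_pcc else NA_real_,
    val_mse = if (nrow(h)) h$val_mse else NA_real_,
    n_parameters = sum(vapply(x$params, length, integer(1)))
  )
}

#' Training-history curves
#'
#' @param object A `sirna_sage` model.
#' @param ... Unused.
#' @return A ggplot of train/validation MSE by epoch, best epoch marked.
#' @method autoplot sirna_sage
#' @export
autoplot.sirna_sage <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                           names_to = "series", values_to = "mse")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$mse,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = "MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-observed efficacy scatter
#'
#' @param data Tibble with truth and estimate columns.
#' @param truth,estimate Column names.
#' @return A ggplot.
#' @export
plot_predictions <- function(data, truth = "efficacy", estimate = ".pred") {
  ggplot2::ggplot(data, ggplot2::aes(.data[[truth]], .data[[estimate]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(x = "observed efficacy", y = "predicted efficacy") +
    ggplot2::theme_minimal()
}

#' Top-k effective-proportion curve
#'
#' For k = 1..n, the percentage of the k highest-predicted pairs whose
#' measured efficacy reaches the cut.
#'
#' @param predictions,labels Numeric vectors.
#' @param efficacy_cut Efficacy threshold (default 0.7).
#' @return A ggplot.
#' @export
plot_top_k <- function(predictions, labels, efficacy_cut = 0.7) {
  ks <- seq_along(predictions)
  prop <- vapply(ks, function(k) {
    top_k_proportion(predictions, labels, k, efficacy_cut)
  }, numeric(1))
  df <- tibble(k = ks, proportion = prop)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$proportion)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 100 * mean(labels >= efficacy_cut),
                        linetype = 2) +
    ggplot2::labs(x = "k (top predictions)",
                  y = paste0("% with efficacy >= ", efficacy_cut)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
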