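#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fit
#'
#' @param x A `tonguecaps_fit`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, `set` (`"train"`/`"val"`), `loss`.
#' @export
tidy.tonguecaps_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, c("train_loss", "val_loss"),
                      names_to = "set", values_to = "loss") |>
    dplyr::mutate(set = sub("_loss$", "", .data$set)) |>
    dplyr::filter(!is.na(.data$loss))
}

#' One-row summary of a fit
#'
#' @param x A `tonguecaps_fit`.
#' @param ... Unused.
#' @return Tibble with the configuration, parameter count, and final
#'   losses.
#' @export
glance.tonguecaps_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = x$config$epochs, batch_size = x$config$batch_size,
                 lr = x$config$lr, optimizer = x$config$optimizer,
                 n_parameters = sum(vapply(x$model$params, length, numeric(1))),
                 final_train_loss = last$train_loss,
                 final_val_loss = last$val_loss)
}

#' Tidy a confusion matrix into long counts
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Tibble with `truth`, `pred`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "pred", "n")
  tibble::as_tibble(df)
}

#' Overall summary of a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return One-row tibble: total count, multiclass accuracy, and the macro
#'   one-vs-rest metrics.
#' @export
glance.confusion_matrix <- function(x, ...) {
  m <- macro_average(metrics_report(x)[seq_len(nrow(x)), ])
  tibble::tibble(n = sum(x), multiclass_accuracy = sum(diag(unclass(x))) / sum(x),
                 macro_accuracy = m$accuracy, macro_sensitivity = m$sensitivity,
                 macro_specificity = m$specificity)
}

#' Plot training and validation loss curves
#'
#' @param object A `tonguecaps_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tonguecaps_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "margin loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heatmap
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(unique(df$truth))) +
    ggplot2::labs(x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}
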