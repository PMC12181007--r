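#' Tidy a fitted model's training history
#'
#' @param x A `ddi_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `epoch`, `metric`
#'   (`train_loss`, `valid_acc`, `valid_auroc`, `valid_f1`) and `value`.
#' @export
tidy.ddi_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "metric",
                      values_to = "value")
}

#' @rdname tidy.ddi_fit
#' @export
glance.ddi_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = max(h$epoch),
    best_epoch = x$best_epoch,
    train_loss_final = h$train_loss[nrow(h)],
    valid_auroc_best = suppressWarnings(max(h$valid_auroc, na.rm = TRUE)),
    n_parameters = sum(vapply(x$model$params, length, integer(1)))
  )
}

#' Tidy an experiment report or ablation table
#'
#' @param x A `ddi_report` or `ddi_ablation`.
#' @param ... Unused.
#' @return The per-run (or per-variant) metric tibble.
#' @export
tidy.ddi_report <- function(x, ...) x$runs

#' @rdname tidy.ddi_report
#' @export
glance.ddi_report <- function(x, ...) x$summary

#' @rdname tidy.ddi_report
#' @export
tidy.ddi_ablation <- function(x, ...) x$results

#' Plot training curves
#'
#' Training loss and validation metrics against the epoch.
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddi_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot an ablation comparison
#'
#' Test metrics for each channel-toggle variant.
#'
#' @param object A `ddi_ablation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddi_ablation <- function(object, ...) {
  d <- tidyr::pivot_longer(object$results[, c("variant", "acc", "auroc", "f1")],
                           -"variant", names_to = "metric",
                           values_to = "value")
  d$variant <- factor(d$variant, levels = object$results$variant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variant, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
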