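# ggplot2 views of training and evaluation results

#' Plot the training history of a fit
#'
#' Training loss and mean validation ROC AUC per epoch, with the
#' checkpointed epoch marked.
#'
#' @param object a `surfibs_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.surfibs_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("best mean validation ROC AUC %.3f (epoch %d)",
                                  object$best_metric, object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot per-protein metric distributions of a report
#'
#' @param object a `surfibs_report`.
#' @param metric `"roc_auc"` or `"mcc"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.surfibs_report <- function(object, metric = "roc_auc", ...) {
  ggplot2::ggplot(object$per_protein,
                  ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::geom_vline(xintercept = median(object$per_protein[[metric]]),
                        linetype = "dashed") +
    ggplot2::labs(x = metric, y = "proteins",
                  title = sprintf("median %s = %.3f (%s level)", metric,
                                  median(object$per_protein[[metric]]),
                                  object$summary$level)) +
    ggplot2::theme_minimal()
}
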