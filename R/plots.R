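#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result objects: per-label F1
#' bars for an evaluation, one-vs-rest ROC curves, the learning curve, the
#' training history of a fitted extractor, and per-stratum incidence rates
#' with their exact confidence intervals.
#'
#' @param object A `cmr_eval`, `cmr_roc`, `cmr_learning_curve`,
#'   `cmr_extractor` or `rate_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-cmrextract
NULL

#' @rdname autoplot-cmrextract
#' @export
autoplot.cmr_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_label,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$f1), y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "token-level F1",
                  title = sprintf("macro-F1 = %.3f", object$macro_f1)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cmrextract
#' @export
autoplot.cmr_roc <- function(object, ...) {
  ggplot2::ggplot(object$curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "measurement") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cmrextract
#' @export
autoplot.cmr_learning_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$size, .data$macro_f1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "annotated reports in training set", y = "macro-F1") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cmrextract
#' @export
autoplot.cmr_extractor <- function(object, ...) {
  h <- tidy(object)
  h_long <- tidyr::pivot_longer(h, c("train_loss", "dev_macro_f1"),
                                names_to = "metric", values_to = "value")
  ggplot2::ggplot(h_long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-cmrextract
#' @export
autoplot.rate_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$stratum, .data$rate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = NULL, y = "incidence rate per 100 person-years") +
    ggplot2::theme_minimal()
}
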