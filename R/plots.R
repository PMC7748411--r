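# ggplot2 views of the package's result objects.

#' Plot a landscape slice
#'
#' Renders a gene x dataset projection of the landscape: one mark per call,
#' sized by the score magnitude and coloured by the interaction sign (blue
#' positive, red negative).
#'
#' @param object a `cs_landscape_slice` from [slice_landscape()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cs_landscape_slice <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dataset, y = .data$gene,
                               size = .data$abs_score, colour = .data$sign)) +
    ggplot2::geom_point(shape = 15) +
    ggplot2::scale_colour_manual(
      values = c("+" = "#2166ac", "-" = "#b2182b", "0" = "grey70")
    ) +
    ggplot2::labs(
      title = paste0("Interaction landscape: ", attr(object, "family")),
      x = NULL, y = NULL, size = "|score|", colour = "sign"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot interaction-category frequencies
#'
#' @param landscape a `cs_landscape`.
#' @return a ggplot bar chart of category proportions over interacting calls.
#' @export
plot_profile_frequencies <- function(landscape) {
  freq <- profile_frequencies(landscape)
  ggplot2::ggplot(freq,
                  ggplot2::aes(x = stats::reorder(.data$category,
                                                  -.data$proportion),
                               y = .data$proportion)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of interacting calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-class precision and recall of a classifier evaluation
#'
#' @param object a `cs_evaluation`.
#' @param ... unused.
#' @return a ggplot of the per-profile precision and recall distributions.
#' @export
autoplot.cs_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class,
                              c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::labs(
      title = sprintf("%s: accuracy %.3f, log gain %.3f",
                      object$model_kind, object$overall_accuracy,
                      object$log_gain),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}
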