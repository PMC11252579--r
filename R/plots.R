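#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a topic-count selection sweep
#'
#' Coherence against candidate topic count, one line per n-gram variant.
#'
#' @param object A `topic_sweep` from [select_num_topics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topic_sweep
#' @export
autoplot.topic_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$K, y = .data$coherence,
                                       colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of topics", y = attr(object, "measure"),
                  colour = "corpus variant") +
    ggplot2::theme_minimal()
}

#' Plot training history of a classifier
#'
#' @param object A trained `neural_model`.
#' @param ... Unused.
#' @return A ggplot object with loss and accuracy panels over epochs.
#' @method autoplot neural_model
#' @export
autoplot.neural_model <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(
      panel = ifelse(grepl("loss", .data$series), "loss", "accuracy"),
      split = ifelse(grepl("train", .data$series), "train", "validation"))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(title = paste(object$spec$arch, "training history")) +
    ggplot2::theme_minimal()
}

#' Plot ROC or PR curves
#'
#' @param object A `classifier_curves` from [roc_pr_curves()].
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object, one curve per class plus the micro average.
#' @method autoplot classifier_curves
#' @export
autoplot.classifier_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                             colour = .data$class)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(linetype = "dashed", alpha = 0.4) +
      ggplot2::labs(x = "false positive rate", y = "true positive rate") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall,
                                            y = .data$precision,
                                            colour = .data$class)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "recall", y = "precision") +
      ggplot2::theme_minimal()
  }
}

#' Bar chart of per-topic shares
#'
#' @param shares A [topic_shares()] tibble.
#' @return A ggplot object.
#' @export
plot_topic_shares <- function(shares) {
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = stats::reorder(.data$label_name,
                                                  -.data$share),
                               y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "share of labeled tweets (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Heat map of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}
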