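#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LDA model
#'
#' @param x A fitted `lda_model`.
#' @param matrix `"beta"` for the topic-word distribution (one row per
#'   topic-term pair) or `"gamma"` for the document-topic distribution.
#' @param ... Unused.
#' @return A tibble in the conventional topic-model tidier layout.
#' @method tidy lda_model
#' @export
tidy.lda_model <- function(x, matrix = c("beta", "gamma"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "beta") {
    tibble::tibble(topic = rep(seq_len(x$K), times = x$V),
                   term = rep(x$vocab, each = x$K),
                   beta = as.vector(x$phi))
  } else {
    tibble::tibble(document = rep(x$doc_ids, times = x$K),
                   topic = rep(seq_len(x$K), each = length(x$doc_ids)),
                   gamma = as.vector(x$theta))
  }
}

#' @method glance lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(K = x$K, V = x$V, n_docs = length(x$doc_ids),
                 n_tokens = sum(x$topic_totals), alpha = x$alpha,
                 beta = x$beta, sweeps = x$sweeps)
}

#' Tidy a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return Long tibble: one row per (class, metric) including `"macro"` and
#'   `"micro"` pseudo-classes.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  metrics <- c("precision", "recall", "f1", "accuracy", "fpr", "specificity")
  per <- x$per_class |>
    dplyr::mutate(class = as.character(.data$class)) |>
    dplyr::select("class", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value")
  agg <- dplyr::bind_rows(
    dplyr::mutate(x$macro, class = "macro"),
    dplyr::mutate(x$micro, class = "micro")) |>
    tidyr::pivot_longer(-"class", names_to = "metric", values_to = "value")
  dplyr::bind_rows(per, agg)
}

#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_precision = x$macro$precision,
                 macro_recall = x$macro$recall, macro_f1 = x$macro$f1,
                 micro_f1 = x$micro$f1)
}

#' @method tidy cv_ttest
#' @export
tidy.cv_ttest <- function(x, ...) x$pairs

#' @method glance cv_ttest
#' @export
glance.cv_ttest <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p_value = x$p_value,
                 threshold = x$threshold, reject = x$reject,
                 zero_variance = x$zero_variance)
}

#' @method tidy neural_model
#' @export
tidy.neural_model <- function(x, ...) x$history

#' @method glance neural_model
#' @export
glance.neural_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(arch = x$spec$arch, n_parameters = x$n_parameters,
                 epochs = nrow(h),
                 final_train_accuracy = if (nrow(h)) h$train_accuracy[nrow(h)] else NA_real_,
                 final_val_accuracy = if (nrow(h)) h$val_accuracy[nrow(h)] else NA_real_)
}

#' @method tidy coherence_score
#' @export
tidy.coherence_score <- function(x, ...) {
  tibble::tibble(topic = seq_along(x$per_topic), score = x$per_topic,
                 measure = x$measure)
}
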