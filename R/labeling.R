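#' Fit tf-idf weights over a bag-of-words corpus
#'
#' Uses the plain scheme `idf(w) = ln(M / df(w))` with within-document term
#' frequency `tf(w, d) = count(w, d) / N_d`. A term present in every document
#' has idf exactly 0 and so never contributes to topic ranking.
#'
#' @param bow A `bow` table from [to_bow()].
#' @return A `tfidf_weights` object: list with `idf` (length-V vector
#'   aligned to vocabulary ids), `M`, and a `scheme` description string.
#' @export
fit_tfidf <- function(bow) {
  vocab <- attr(bow, "vocab")
  V <- attr(vocab, "V")
  M <- length(attr(bow, "doc_ids"))
  if (M < 1) tt_abort("fit_tfidf: empty corpus")
  df <- tabulate(bow$term_id[!duplicated(paste(bow$id, bow$term_id))],
                 nbins = V)
  idf <- ifelse(df > 0, log(M / df), 0)
  structure(list(idf = idf, M = M,
                 scheme = "tf = count/N_d; idf = ln(M/df); no smoothing"),
            class = "tfidf_weights")
}

#' Dominant-topic scores and labels for documents
#'
#' The topic-ranking rule at the heart of the automatic annotation: a
#' document's affinity for topic `k` is the tf-idf-weighted expected
#' topic-word probability
#' `score(d, k) = sum_w tfidf(w, d) * phi_kw`,
#' and the document's class label is the arg-max topic (ties break to the
#' smallest topic index). Documents with no in-vocabulary tokens, or whose
#' every term has zero tf-idf weight, carry no ranking signal: they are
#' flagged `unlabelable` (label `NA`) and should be excluded from classifier
#' training while still being countable in aggregates.
#'
#' The labels are invariant to rescaling all tf-idf weights by any positive
#' constant.
#'
#' @param bow A `bow` table over the model's vocabulary.
#' @param model A fitted `lda_model`.
#' @param weights A `tfidf_weights` object from [fit_tfidf()].
#' @return A tibble with one row per document: `id`, `label` (integer or
#'   `NA`), `unlabelable`, and the length-`K` `topic_scores` list column.
#' @export
dominant_topic <- function(bow, model, weights) {
  stopifnot(inherits(model, "lda_model"), inherits(weights, "tfidf_weights"))
  vocab <- attr(bow, "vocab")
  if (attr(vocab, "V") != model$V ||
      !identical(vocab$term, model$vocab)) {
    tt_abort("dominant_topic: bow vocabulary does not match the model")
  }
  if (length(weights$idf) != model$V) {
    tt_abort("dominant_topic: tf-idf weights do not match the vocabulary")
  }
  X <- bow_matrix(bow)                      # docs x V raw counts
  N_d <- Matrix::rowSums(X)
  tf <- X / pmax(N_d, 1)
  tfidf <- tf %*% Matrix::Diagonal(x = weights$idf)
  S <- as.matrix(tfidf %*% t(model$phi))    # docs x K
  unlabelable <- Matrix::rowSums(abs(tfidf)) == 0
  label <- max.col(S, ties.method = "first")
  label[unlabelable] <- NA_integer_
  tibble::tibble(id = attr(bow, "doc_ids"),
                 label = as.integer(label),
                 unlabelable = unname(unlabelable),
                 topic_scores = lapply(seq_len(nrow(S)),
                                       function(i) unname(S[i, ])))
}

#' Label a corpus with its dominant topics
#'
#' Applies [dominant_topic()] to every document and joins the labels back
#' onto the tweet corpus, adding `label`, `label_name`, `unlabelable` and
#' `topic_scores` columns. A per-class summary (counts and shares of
#' labelable tweets) is attached as attribute `"summary"`.
#'
#' @param corpus A corpus tibble.
#' @param bow The corpus's `bow` representation (same document ids).
#' @param model A fitted `lda_model`.
#' @param weights [fit_tfidf()] weights.
#' @param topic_names Length-`K` character vector of class names
#'   (default [covid_topic_names()]).
#' @return The labeled corpus tibble.
#' @export
label_corpus <- function(corpus, bow, model, weights,
                         topic_names = covid_topic_names(model$K)) {
  if (length(topic_names) != model$K) {
    tt_abort(sprintf("topic_names must have K = %d entries", model$K))
  }
  lab <- dominant_topic(bow, model, weights)
  out <- dplyr::left_join(corpus, lab, by = "id")
  out$label_name <- ifelse(is.na(out$label), NA_character_,
                           topic_names[out$label])
  labelable <- out[!is.na(out$label), ]
  summary <- labelable |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(label_name = topic_names[.data$label],
                  share = .data$n / sum(.data$n)) |>
    dplyr::select("label", "label_name", "n", "share")
  attr(out, "summary") <- summary
  attr(out, "n_unlabelable") <- sum(out$unlabelable)
  out
}
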