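# Sliding-window co-occurrence counts over reference token documents.
# Documents shorter than the window contribute a single window (the whole
# document). Returns boolean occurrence counts: in how many windows each
# tracked word, and each pair of tracked words, appears.
window_counts <- function(reference_docs, words, window) {
  W <- length(words)
  word_wins <- numeric(W)
  pair_wins <- matrix(0, W, W)
  n_windows <- 0
  for (tk in reference_docs) {
    L <- length(tk)
    if (L == 0) next
    idx <- match(tk, words)  # NA for untracked tokens
    if (L <= window) {
      wins <- list(idx)
    } else {
      wins <- lapply(seq_len(L - window + 1),
                     function(s) idx[s:(s + window - 1)])
    }
    for (win in wins) {
      present <- sort(unique(win[!is.na(win)]))
      n_windows <- n_windows + 1
      if (length(present) == 0) next
      word_wins[present] <- word_wins[present] + 1
      pair_wins[present, present] <- pair_wins[present, present] + 1
    }
  }
  list(word_wins = word_wins, pair_wins = pair_wins, n_windows = n_windows)
}

# NPMI between two tracked words from window counts; eps floors the joint
# probability inside the logs. Perfect co-occurrence (joint equals both
# marginals, positive) is the limit value +1 and is returned exactly; a word
# absent from every window carries no information and scores 0.
npmi_pair <- function(p_i, p_j, p_ij, eps) {
  if (p_i == 0 || p_j == 0) return(0)
  if (p_ij == p_i && p_ij == p_j) return(1)
  log((p_ij + eps) / (p_i * p_j)) / -log(p_ij + eps)
}

npmi_matrix <- function(cnt, eps) {
  W <- length(cnt$word_wins)
  P <- cnt$word_wins / cnt$n_windows
  Pij <- cnt$pair_wins / cnt$n_windows
  out <- matrix(0, W, W)
  for (i in seq_len(W)) {
    for (j in seq_len(W)) {
      out[i, j] <- npmi_pair(P[i], P[j], Pij[i, j], eps)
    }
  }
  out
}

#' Topic coherence: C_V and NPMI measures
#'
#' Estimates word and word-pair probabilities as boolean sliding-window
#' frequencies over the reference documents (window size `window`; documents
#' shorter than the window form one window), computes
#' `NPMI(wi, wj) = ln((P(wi,wj) + eps) / (P(wi) P(wj))) / -ln(P(wi,wj) + eps)`
#' and aggregates per topic:
#'
#' * `c_npmi` - the mean NPMI over the `choose(N, 2)` pairs `i < j` of the
#'   topic's top-`N` words (each per-topic value in `[-1, 1]`);
#' * `c_v` - one-set segmentation: each top word's NPMI context vector over
#'   the top-`N` set is compared by cosine similarity with the sum vector of
#'   the whole set, and similarities are averaged over words.
#'
#' The overall `value` is the arithmetic mean of the per-topic scores.
#'
#' @param topics A list of character vectors (top terms per topic), or a
#'   [top_words()] tibble.
#' @param reference_docs A token-document tibble or a list of token vectors.
#' @param measure `"c_v"` (default) or `"c_npmi"`.
#' @param window Sliding window size (default 110).
#' @param top_n Number of top words per topic entering the score (default 10).
#' @param eps Floor inside the NPMI logarithms (default 1e-12).
#' @return A `coherence_score` object: list with `measure`, `value`,
#'   `per_topic`, `top_n`, `window`.
#' @export
coherence <- function(topics, reference_docs, measure = c("c_v", "c_npmi"),
                      window = 110, top_n = 10, eps = 1e-12) {
  measure <- match.arg(measure)
  if (is.data.frame(topics)) {
    topics <- split(topics$term, topics$topic)
  }
  topics <- lapply(topics, head, top_n)
  if (any(lengths(topics) < 2)) {
    tt_abort("coherence: every topic needs at least 2 terms")
  }
  if (is.data.frame(reference_docs)) reference_docs <- reference_docs$tokens
  if (length(reference_docs) == 0) {
    tt_abort("coherence: reference documents required")
  }

  per_topic <- vapply(topics, function(words) {
    words <- unique(words)
    cnt <- window_counts(reference_docs, words, window)
    npmi <- npmi_matrix(cnt, eps)
    N <- length(words)
    if (measure == "c_npmi") {
      pairs <- which(upper.tri(npmi), arr.ind = TRUE)
      mean(npmi[pairs])
    } else {
      agg <- colSums(npmi)  # sum context vector of the whole set
      sims <- vapply(seq_len(N), function(i) {
        v <- npmi[i, ]
        den <- sqrt(sum(v^2)) * sqrt(sum(agg^2))
        if (den == 0) return(0)
        sum(v * agg) / den
      }, numeric(1))
      mean(sims)
    }
  }, numeric(1))

  structure(list(measure = measure, value = mean(per_topic),
                 per_topic = unname(per_topic), top_n = top_n,
                 window = window),
            class = "coherence_score")
}

#' @export
print.coherence_score <- function(x, ...) {
  cat(sprintf("<coherence %s = %.4f over %d topics (top_n = %d, window = %d)>\n",
              x$measure, x$value, length(x$per_topic), x$top_n, x$window))
  invisible(x)
}

#' Topic-count selection sweep
#'
#' Fits one LDA model per candidate `K` and n-gram variant, scores each with
#' [coherence()] against the (variant-transformed) reference documents, and
#' reports a tidy sweep table with the best-scoring configuration attached.
#' A failed fit is recorded as an `NA` row rather than aborting the sweep.
#'
#' @param docs A token-document tibble (unigram form).
#' @param candidate_K Integer vector of at least two candidate topic counts.
#' @param variants Subset of `c("unigram", "bigram", "trigram")`.
#' @param measure,window,top_n Passed to [coherence()].
#' @param min_count,threshold Phrase-detection settings for the bigram /
#'   trigram variants.
#' @param min_df,max_df_frac Vocabulary pruning settings.
#' @param seed Base seed; each (K, variant) fit uses a distinct seed derived
#'   from it, so the sweep is deterministic.
#' @param ... Further arguments to [fit_lda()] (e.g. `sweeps`, `alpha`).
#' @return A `topic_sweep` tibble with columns `K`, `variant`, `coherence`
#'   and a `per_topic` list column; the best row index is attribute
#'   `"best"`.
#' @export
select_num_topics <- function(docs, candidate_K,
                              variants = "unigram",
                              measure = "c_v", window = 110, top_n = 10,
                              min_count = 5, threshold = 10,
                              min_df = 1, max_df_frac = 1.0,
                              seed = 1, ...) {
  if (length(candidate_K) < 2) {
    tt_abort("select_num_topics: need at least 2 candidate topic counts")
  }
  variants <- match.arg(variants, c("unigram", "bigram", "trigram"),
                        several.ok = TRUE)
  grid <- tidyr::expand_grid(variant = variants, K = sort(candidate_K))
  variant_docs <- list(unigram = docs)
  if ("bigram" %in% variants || "trigram" %in% variants) {
    bi <- fit_phrases(docs, min_count = min_count, threshold = threshold,
                      order = "bigram")
    variant_docs$bigram <- apply_phrases(bi, docs)
  }
  if ("trigram" %in% variants) {
    tri <- fit_phrases(docs, min_count = min_count, threshold = threshold,
                       order = "trigram")
    variant_docs$trigram <- apply_phrases(tri, docs)
  }

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    K <- grid$K[i]; variant <- grid$variant[i]
    fit_seed <- (seed + 7919L * i) %% .Machine$integer.max
    res <- tryCatch({
      vdocs <- variant_docs[[variant]]
      vocab <- build_vocabulary(vdocs, min_df = min_df,
                                max_df_frac = max_df_frac)
      bow <- to_bow(vdocs, vocab)
      model <- fit_lda(bow, K = K, seed = fit_seed, ...)
      tw <- top_words(model, n = top_n)
      coh <- coherence(tw, vdocs, measure = measure, window = window,
                       top_n = top_n)
      tibble::tibble(K = K, variant = variant, coherence = coh$value,
                     per_topic = list(coh$per_topic))
    }, error = function(e) {
      tt_inform(sprintf("select_num_topics: K = %d, %s failed: %s",
                        K, variant, conditionMessage(e)))
      tibble::tibble(K = K, variant = variant, coherence = NA_real_,
                     per_topic = list(numeric()))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "best") <- if (all(is.na(out$coherence))) NA_integer_ else
    which.max(out$coherence)
  attr(out, "measure") <- measure
  class(out) <- c("topic_sweep", class(out))
  out
}
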