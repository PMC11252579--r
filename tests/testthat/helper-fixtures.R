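# Shared fixtures and independent oracles. The oracle implementations are
# deliberately written as direct, brute-force enumerations sharing no code
# with the package internals they check.

options(tweettopics.quiet = TRUE)

# tiny vocabulary builder
toy_vocab <- function(terms) {
  terms <- sort(terms, method = "radix")
  v <- tibble::tibble(term = terms, id = seq_along(terms),
                      df = rep(1L, length(terms)))
  attr(v, "V") <- length(terms)
  attr(v, "M") <- 1L
  class(v) <- c("vocabulary", class(v))
  v
}

toy_docs <- function(token_lists, ids = NULL) {
  if (is.null(ids)) ids <- paste0("d", seq_along(token_lists))
  tibble::tibble(id = ids, tokens = token_lists,
                 empty = lengths(token_lists) == 0)
}

# hand-built lda_model carrying a given phi (for labeling tests that need a
# known topic-word matrix without running Gibbs)
toy_lda_model <- function(phi, vocab) {
  structure(list(K = nrow(phi), V = ncol(phi), alpha = 0.1, beta = 0.01,
                 phi = phi, theta = NULL, topic_word_counts = round(phi * 1000),
                 topic_totals = rep(1000, nrow(phi)), doc_topic_counts = NULL,
                 assignments = NULL, vocab = vocab$term, doc_ids = NULL,
                 sweeps = 0, burn_in = 0, estimate = "final", seed = NULL),
            class = "lda_model")
}

# greedy best-match topic alignment between two topic-word matrices; returns
# the per-match cosines (used for parameter recovery checks)
greedy_match_cosines <- function(phi_fit, phi_true) {
  cosr <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  K <- nrow(phi_fit)
  S <- outer(seq_len(K), seq_len(K),
             Vectorize(function(i, j) cosr(phi_fit[i, ], phi_true[j, ])))
  sims <- numeric(K)
  map <- integer(K)
  for (s in seq_len(K)) {
    ij <- which(S == max(S), arr.ind = TRUE)[1, ]
    sims[s] <- S[ij[1], ij[2]]
    map[ij[1]] <- ij[2]
    S[ij[1], ] <- -Inf
    S[, ij[2]] <- -Inf
  }
  list(cosines = sims, map = map)
}

## ---- coherence oracle (direct window enumeration) -------------------------

oracle_windows <- function(docs, window) {
  wins <- list()
  for (tk in docs) {
    L <- length(tk)
    if (L == 0) next
    if (L <= window) {
      wins <- c(wins, list(unique(tk)))
    } else {
      for (s in 1:(L - window + 1)) {
        wins <- c(wins, list(unique(tk[s:(s + window - 1)])))
      }
    }
  }
  wins
}

oracle_npmi <- function(wins, a, b, eps = 1e-12) {
  N <- length(wins)
  pa <- sum(vapply(wins, function(w) a %in% w, logical(1))) / N
  pb <- sum(vapply(wins, function(w) b %in% w, logical(1))) / N
  pab <- sum(vapply(wins, function(w) a %in% w && b %in% w, logical(1))) / N
  if (pa == 0 || pb == 0) return(0)
  if (pab == pa && pab == pb) return(1)
  log((pab + eps) / (pa * pb)) / -log(pab + eps)
}

oracle_coherence <- function(topics, docs, measure, window, eps = 1e-12) {
  wins <- oracle_windows(docs, window)
  per <- vapply(topics, function(ws) {
    N <- length(ws)
    M <- outer(seq_len(N), seq_len(N),
               Vectorize(function(i, j) oracle_npmi(wins, ws[i], ws[j], eps)))
    if (measure == "c_npmi") {
      vals <- c()
      for (i in 1:(N - 1)) for (j in (i + 1):N) vals <- c(vals, M[i, j])
      mean(vals)
    } else {
      agg <- colSums(M)
      mean(vapply(seq_len(N), function(i) {
        v <- M[i, ]
        d <- sqrt(sum(v^2)) * sqrt(sum(agg^2))
        if (d == 0) 0 else sum(v * agg) / d
      }, numeric(1)))
    }
  }, numeric(1))
  mean(per)
}

## ---- metric oracles (direct one-vs-rest counting) -------------------------

oracle_binary_metrics <- function(y_true, y_pred, cls) {
  tp <- sum(y_true == cls & y_pred == cls)
  fp <- sum(y_true != cls & y_pred == cls)
  fn <- sum(y_true == cls & y_pred != cls)
  tn <- sum(y_true != cls & y_pred != cls)
  div <- function(a, b) if (b == 0) 0 else a / b
  p <- div(tp, tp + fp); r <- div(tp, tp + fn)
  list(precision = p, recall = r, f1 = div(2 * p * r, p + r),
       accuracy = div(tp + tn, tp + tn + fp + fn),
       fpr = div(fp, fp + tn))
}

# all-pairs Mann-Whitney probability: P(score_pos > score_neg) + 0.5 ties
oracle_auc_mw <- function(y, s) {
  pos <- s[y]; neg <- s[!y]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

## ---- misc -----------------------------------------------------------------

# a tiny well-separated bundle for classifier tests
separable_bundle <- function(D = 600, K = 5, V = 250, seed = 17) {
  sample_corpus(generator_config(
    K_true = K, V = V, D = D, alpha = 0.01, beta = 0.01,
    doc_length_lambda = 20, seed = seed, p_pos = 0, p_neg = 0,
    hashtag_max = 0, disjoint_topics = TRUE))
}

small_embeddings <- function(vocab, dim = 32, seed = 2) {
  build_embeddings(vocab, dim = dim, seed = seed)
}
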