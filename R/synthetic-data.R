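# Dirichlet sampler built on rgamma (one row per draw)
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  x <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  x / rowSums(x)
}

#' Default country table for the synthetic generator
#'
#' A dozen ISO-3166 alpha-2 codes with rough 2021 populations and sampling
#' weights; one "" entry emulates tweets without an account location.
#'
#' @return A tibble with `country`, `population`, `weight`.
#' @export
default_country_table <- function() {
  tibble::tibble(
    country = c("us", "gb", "in", "ca", "au", "de", "fr", "br", "za", "ir",
                "cn", ""),
    population = c(331e6, 67e6, 1380e6, 38e6, 26e6, 83e6, 67e6, 213e6,
                   60e6, 85e6, 1412e6, NA),
    weight = c(0.30, 0.12, 0.10, 0.05, 0.04, 0.05, 0.04, 0.06, 0.03, 0.03,
               0.03, 0.15))
}

#' Configuration of the synthetic tweet generator
#'
#' Describes a fully known Dirichlet-multinomial topic process that emulates
#' a short-document crisis corpus: `phi*_k ~ Dirichlet(beta)` over a
#' pseudo-word vocabulary, `theta*_d ~ Dirichlet(alpha)` (optionally tilted
#' by `topic_weights`; the concentration vector is `alpha * K *
#' topic_weights`, so uniform weights recover the symmetric
#' `Dirichlet(alpha)`), token counts truncated-Poisson document lengths,
#' per-document countries, hashtag decoration drawn from the crisis keyword
#' list, and sentiment words injected per topic.
#'
#' @param K_true Number of generating topics (default 10).
#' @param V Vocabulary size (default 500; a warning is given below
#'   `10 * K_true`, where topics separate poorly).
#' @param D Number of documents (default 2000).
#' @param alpha Document-topic concentration (default 0.1; small values make
#'   documents concentrate on one topic).
#' @param beta Topic-word concentration (default 0.01).
#' @param doc_length_lambda Poisson mean document length (default 20).
#' @param doc_length_range Inclusive truncation bounds (default `c(3, 50)`).
#' @param topic_weights Optional length-`K_true` expected topic shares
#'   (default uniform); must be non-negative and sum to 1.
#' @param countries Country table with `country`, `population`, `weight`.
#' @param p_pos,p_neg Per-topic probabilities of injecting positive /
#'   negative sentiment words (scalars are recycled; default 0.25 each).
#' @param lexicon Sentiment lexicon used for injection.
#' @param hashtag_max Maximum hashtags appended per tweet (default 2).
#' @param planted_phrases Optional character vector of fixed adjacent token
#'   pairs (e.g. `"stay home"`) planted to exercise phrase detection.
#' @param planted_prob Per-document probability of planting each phrase.
#' @param disjoint_topics If `TRUE`, each topic's word distribution is
#'   supported on its own contiguous block of the vocabulary (blocks of
#'   size `floor(V / K_true)`), giving a well-separated corpus where
#'   classes share no words. Default `FALSE` (full-support Dirichlet
#'   topics).
#' @param seed Integer seed; the whole bundle regenerates bit-identically
#'   from (config, seed).
#' @return A `generator_config` object.
#' @export
generator_config <- function(K_true = 10, V = 500, D = 2000,
                             alpha = 0.1, beta = 0.01,
                             doc_length_lambda = 20,
                             doc_length_range = c(3, 50),
                             topic_weights = NULL,
                             countries = default_country_table(),
                             p_pos = 0.25, p_neg = 0.25,
                             lexicon = default_sentiment_lexicon(),
                             hashtag_max = 2,
                             planted_phrases = NULL, planted_prob = 0,
                             disjoint_topics = FALSE,
                             seed = 1) {
  if (is.null(topic_weights)) topic_weights <- rep(1 / K_true, K_true)
  if (length(topic_weights) != K_true || any(topic_weights < 0) ||
      abs(sum(topic_weights) - 1) > 1e-8) {
    tt_abort("topic_weights must be length K_true, non-negative, summing to 1")
  }
  if (doc_length_lambda <= 0) tt_abort("doc_length_lambda must be > 0")
  p_pos <- rep_len(p_pos, K_true); p_neg <- rep_len(p_neg, K_true)
  if (any(p_pos < 0 | p_pos > 1 | p_neg < 0 | p_neg > 1 |
          p_pos + p_neg > 1)) {
    tt_abort("sentiment injection probabilities must lie in [0, 1] with p_pos + p_neg <= 1")
  }
  if (V < 10 * K_true) {
    warning("V < 10 * K_true: topics may separate poorly", call. = FALSE)
  }
  structure(list(K_true = K_true, V = V, D = D, alpha = alpha, beta = beta,
                 doc_length_lambda = doc_length_lambda,
                 doc_length_range = doc_length_range,
                 topic_weights = topic_weights, countries = countries,
                 p_pos = p_pos, p_neg = p_neg, lexicon = lexicon,
                 hashtag_max = hashtag_max,
                 planted_phrases = planted_phrases,
                 planted_prob = planted_prob,
                 disjoint_topics = disjoint_topics, seed = seed),
            class = "generator_config")
}

rtrunc_pois <- function(n, lambda, range) {
  out <- integer(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rpois(length(need), lambda)
    ok <- draw >= range[1] & draw <= range[2]
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic tweet corpus with full ground truth
#'
#' Draws a corpus from the generative topic process declared in a
#' [generator_config()]: topic-word distributions `phi*`, per-document topic
#' proportions `theta*`, token topic assignments and pseudo-word tokens
#' (`w0001` style), then decorates each document into a tweet record
#' (country, hashtags, injected sentiment words, metadata compliant with the
#' default [filter_spec()]). All draws come from one seeded generator, so
#' the bundle is bit-reproducible.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_bundle`: list with `tweets` (corpus tibble),
#'   `tokens` (token-document tibble including injected sentiment words),
#'   `word_ids` (list of the LDA-generated vocabulary ids per document),
#'   `z` (list of token topic assignments), `phi` (`K x V`), `theta`
#'   (`D x K`), `truth` (tibble: `id`, `topic` = argmax of `theta*_d`,
#'   `sentiment`, `country`), `vocab_terms`, and the `config`.
#' @export
sample_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  K <- config$K_true; V <- config$V; D <- config$D
  vocab_terms <- sprintf("w%04d", seq_len(V))

  if (isTRUE(config$disjoint_topics)) {
    block <- floor(V / K)
    phi <- matrix(0, K, V)
    for (k in seq_len(K)) {
      cols <- ((k - 1) * block + 1):(k * block)
      phi[k, cols] <- rdirichlet(1, rep(config$beta, length(cols)))
    }
  } else {
    phi <- rdirichlet(K, rep(config$beta, V))
  }
  conc <- config$alpha * K * config$topic_weights
  theta <- rdirichlet(D, conc)
  lens <- rtrunc_pois(D, config$doc_length_lambda, config$doc_length_range)

  cn <- config$countries
  country <- sample(cn$country, D, replace = TRUE, prob = cn$weight)
  tags_pool <- covid_keywords()
  sent_terms <- split(config$lexicon$term, config$lexicon$polarity)

  word_ids <- vector("list", D)
  z_list <- vector("list", D)
  tokens <- vector("list", D)
  hashtags <- vector("list", D)
  sentiment <- character(D)
  texts <- character(D)
  t0 <- as.POSIXct("2020-12-01", tz = "UTC")
  created <- t0 + runif(D, 0, 243 * 86400)

  for (d in seq_len(D)) {
    z <- sample.int(K, lens[d], replace = TRUE, prob = theta[d, ])
    w <- integer(lens[d])
    for (k in sort(unique(z))) {
      idx <- which(z == k)
      w[idx] <- sample.int(V, length(idx), replace = TRUE, prob = phi[k, ])
    }
    z_list[[d]] <- z
    word_ids[[d]] <- w
    tk <- vocab_terms[w]
    if (!is.null(config$planted_phrases) && config$planted_prob > 0) {
      for (ph in config$planted_phrases) {
        if (runif(1) < config$planted_prob) {
          pos <- sample.int(length(tk) + 1, 1)
          tk <- append(tk, strsplit(ph, "\\s+")[[1]], after = pos - 1)
        }
      }
    }
    topic_d <- which.max(theta[d, ])
    u <- runif(1)
    if (u < config$p_pos[topic_d]) {
      sentiment[d] <- "positive"
      tk <- c(tk, sample(sent_terms$pos, 2))
    } else if (u < config$p_pos[topic_d] + config$p_neg[topic_d]) {
      sentiment[d] <- "negative"
      tk <- c(tk, sample(sent_terms$neg, 2))
    } else {
      sentiment[d] <- "neutral"
    }
    tokens[[d]] <- tk
    n_tags <- sample.int(config$hashtag_max + 1, 1) - 1L
    tags <- if (n_tags > 0) sample(tags_pool, n_tags) else character()
    hashtags[[d]] <- tags
    texts[d] <- paste(c(tk, if (length(tags)) paste0("#", tags)),
                      collapse = " ")
  }

  ids <- sprintf("t%06d", seq_len(D))
  tweets <- tibble::tibble(
    id = ids, text = texts, lang = "en", country = country,
    created_at = format(created, "%Y-%m-%dT%H:%M:%SZ"),
    hashtags = hashtags,
    retweet_count = rpois(D, 2),
    is_retweet = FALSE, is_reply = FALSE, is_quote = FALSE)

  truth <- tibble::tibble(id = ids,
                          topic = apply(theta, 1, which.max),
                          sentiment = sentiment, country = country)

  structure(list(tweets = tweets,
                 tokens = tibble::tibble(id = ids, tokens = tokens,
                                         empty = lengths(tokens) == 0),
                 word_ids = word_ids, z = z_list,
                 phi = phi, theta = theta, truth = truth,
                 vocab_terms = vocab_terms, config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle: D = %d docs, K_true = %d, V = %d, seed = %d>\n",
              x$config$D, x$config$K_true, x$config$V, x$config$seed))
  invisible(x)
}

#' Bag-of-words table of a bundle's ground-truth tokens
#'
#' Builds the `bow` representation directly from the generator's sampled
#' vocabulary ids (no text round trip), with the generator's own vocabulary.
#' Convenient for parameter-recovery experiments.
#'
#' @param bundle A `synthetic_bundle`.
#' @return A `bow` table over the generator vocabulary.
#' @export
bundle_bow <- function(bundle) {
  docs <- tibble::tibble(
    id = bundle$truth$id,
    tokens = lapply(bundle$word_ids, function(w) bundle$vocab_terms[w]),
    empty = lengths(bundle$word_ids) == 0)
  vocab <- tibble::tibble(term = bundle$vocab_terms,
                          id = seq_along(bundle$vocab_terms),
                          df = vapply(seq_along(bundle$vocab_terms),
                                      function(j) 1L, integer(1)))
  df_tab <- table(unlist(lapply(docs$tokens, unique), use.names = FALSE))
  vocab$df <- as.integer(df_tab[vocab$term])
  vocab$df[is.na(vocab$df)] <- 0L
  attr(vocab, "V") <- nrow(vocab)
  attr(vocab, "M") <- nrow(docs)
  class(vocab) <- c("vocabulary", class(vocab))
  to_bow(docs, vocab)
}

#' Write a synthetic bundle to disk
#'
#' Emits `tweets.jsonl`, `truth_phi.csv`, `truth_theta.csv`,
#' `truth_labels.csv`, `populations.csv` and `lexicon.csv` into a
#' directory; `tweets.jsonl` is re-readable by [read_tweets()] and passes
#' the default [filter_spec()] untouched.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tweets(bundle$tweets, file.path(dir, "tweets.jsonl"), "jsonl")
  utils::write.csv(bundle$phi, file.path(dir, "truth_phi.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$theta, file.path(dir, "truth_theta.csv"),
                   row.names = FALSE)
  readr::write_csv(bundle$truth, file.path(dir, "truth_labels.csv"),
                   progress = FALSE)
  pops <- bundle$config$countries[bundle$config$countries$country != "",
                                  c("country", "population")]
  readr::write_csv(pops, file.path(dir, "populations.csv"), progress = FALSE)
  readr::write_csv(bundle$config$lexicon, file.path(dir, "lexicon.csv"),
                   progress = FALSE)
  invisible(dir)
}
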