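#' Tokenize raw tweet text
#'
#' Lowercases the text, removes URLs, @-mentions and standalone punctuation,
#' strips `#` from hashtags (the tag word itself is kept), then extracts
#' tokens as maximal runs of letters, digits, underscore or apostrophe.
#' Hyphens therefore split tokens (`"covid-19"` becomes `"covid"`, `"19"`).
#' Stopwords are removed last.
#'
#' @param text Character vector of raw texts.
#' @param stopwords Character vector of stopwords to drop
#'   (default [stopwords_en()]); use `character()` to keep everything.
#' @return A list of character token vectors, one per input text.
#' @export
tokenize_text <- function(text, stopwords = stopwords_en()) {
  cleaned <- tolower(text)
  cleaned <- stringr::str_replace_all(cleaned, "(https?://|www\\.)\\S+", " ")
  cleaned <- stringr::str_replace_all(cleaned, "@\\w+", " ")
  cleaned <- stringr::str_replace_all(cleaned, "#", " ")
  toks <- stringr::str_extract_all(cleaned, "[a-z0-9_']+")
  lapply(toks, function(tk) {
    tk <- tk[grepl("[a-z0-9]", tk)]        # drop bare apostrophe runs
    tk <- gsub("^'+|'+$", "", tk)          # trim wrapping quotes
    tk <- tk[nzchar(tk)]
    tk[!tk %in% stopwords]
  })
}

#' Tokenize a corpus into token documents
#'
#' @param corpus A corpus tibble (needs `id` and `text`).
#' @param stopwords Stopword vector passed to [tokenize_text()].
#' @return A tibble with `id` and a `tokens` list column; empty documents are
#'   kept and flagged in the logical `empty` column.
#' @export
tokenize_corpus <- function(corpus, stopwords = stopwords_en()) {
  toks <- tokenize_text(corpus$text, stopwords = stopwords)
  tibble::tibble(id = corpus$id, tokens = toks, empty = lengths(toks) == 0)
}

#' Bundled lemma lexicon
#'
#' A small built-in surface-form -> (lemma, part-of-speech) table covering
#' common pandemic-domain inflections, used as the default for
#' [lemmatize_tokens()]. Users supply a larger table as a CSV with columns
#' `surface`, `lemma`, `pos` via [read_lemma_lexicon()]. Tokens absent from
#' the lexicon keep their surface form and are treated as nouns.
#'
#' @return A tibble with columns `surface`, `lemma`, `pos`.
#' @export
lemma_lexicon <- function() {
  path <- system.file("extdata", "lemma_lexicon.csv", package = "tweettopics")
  read_lemma_lexicon(path)
}

#' Read a lemma lexicon from CSV
#'
#' @param path CSV with columns `surface`, `lemma`, `pos`; `pos` values are
#'   `noun`, `verb`, `adjective`, `adverb` or `other`.
#' @return A lexicon tibble.
#' @export
read_lemma_lexicon <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    surface = readr::col_character(), lemma = readr::col_character(),
    pos = readr::col_character()), progress = FALSE)
  tibble::as_tibble(df[, c("surface", "lemma", "pos")])
}

#' Lemmatize and POS-filter token documents
#'
#' Replaces each token by its lemma and drops tokens whose part of speech is
#' outside `pos_keep`. Lemmatization is a lookup against a lexicon table;
#' out-of-lexicon tokens fall back to identity with `pos = "noun"` (so they
#' are retained under the default filter).
#'
#' @param docs A token-document tibble from [tokenize_corpus()].
#' @param lexicon A lexicon tibble (default the bundled [lemma_lexicon()]).
#' @param pos_keep Parts of speech to keep; default nouns, adjectives and
#'   verbs, the content classes most informative for topic modeling.
#' @return The token-document tibble with lemmatized, filtered `tokens`.
#' @export
lemmatize_tokens <- function(docs, lexicon = lemma_lexicon(),
                             pos_keep = c("noun", "adjective", "verb")) {
  lemma_of <- setNames(lexicon$lemma, lexicon$surface)
  pos_of <- setNames(lexicon$pos, lexicon$surface)
  docs$tokens <- lapply(docs$tokens, function(tk) {
    if (length(tk) == 0) return(tk)
    lem <- lemma_of[tk]
    pos <- pos_of[tk]
    lem[is.na(lem)] <- tk[is.na(lem)]
    pos[is.na(pos)] <- "noun"
    unname(lem[pos %in% pos_keep])
  })
  docs$empty <- lengths(docs$tokens) == 0
  docs
}

pair_counts <- function(token_list) {
  uni <- table(unlist(token_list, use.names = FALSE))
  pairs <- lapply(token_list, function(tk) {
    if (length(tk) < 2) return(NULL)
    paste(tk[-length(tk)], tk[-1], sep = "\x01")
  })
  bi <- table(unlist(pairs, use.names = FALSE))
  list(uni = uni, bi = bi, V = length(uni))
}

score_pairs <- function(cnt, min_count, threshold) {
  if (length(cnt$bi) == 0) {
    return(tibble::tibble(a = character(), b = character(),
                          score = numeric()))
  }
  ab <- as.numeric(cnt$bi)
  parts <- stringr::str_split_fixed(names(cnt$bi), "\x01", 2)
  a <- parts[, 1]; b <- parts[, 2]
  score <- (ab - min_count) * cnt$V / (as.numeric(cnt$uni[a]) * as.numeric(cnt$uni[b]))
  keep <- score >= threshold
  tibble::tibble(a = a[keep], b = b[keep], score = score[keep])
}

#' Detect bigram / trigram phrases
#'
#' Scores every adjacent token pair `(a, b)` across the corpus with
#' `score = (count(a, b) - min_count) * V / (count(a) * count(b))`, where `V`
#' is the number of distinct tokens; pairs scoring at least `threshold`
#' become phrases joined as `"a_b"`. A trigram model applies a second
#' identical pass over the bigram-transformed corpus so that e.g.
#' `"stay_home" + "safe"` can merge into `"stay_home_safe"`.
#'
#' @param docs A token-document tibble.
#' @param min_count Minimum pair count (default 5).
#' @param threshold Minimum phrase score (default 10).
#' @param order `"bigram"` or `"trigram"`.
#' @return A `phrase_model` with one (`bigram`) or two (`trigram`) scoring
#'   passes.
#' @export
fit_phrases <- function(docs, min_count = 5, threshold = 10,
                        order = c("bigram", "trigram")) {
  order <- match.arg(order)
  if (min_count < 1) tt_abort("min_count must be >= 1")
  if (threshold <= 0) tt_abort("threshold must be > 0")
  if (nrow(docs) == 0) tt_abort("fit_phrases: empty document set")
  passes <- list(score_pairs(pair_counts(docs$tokens), min_count, threshold))
  if (order == "trigram") {
    model1 <- structure(list(order = "bigram", min_count = min_count,
                             threshold = threshold, passes = passes),
                        class = "phrase_model")
    transformed <- apply_phrases(model1, docs)
    passes <- c(passes, list(score_pairs(pair_counts(transformed$tokens),
                                         min_count, threshold)))
  }
  structure(list(order = order, min_count = min_count, threshold = threshold,
                 passes = passes), class = "phrase_model")
}

merge_pass <- function(tk, phrase_set) {
  n <- length(tk)
  if (n < 2 || length(phrase_set) == 0) return(tk)
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (i < n && paste(tk[i], tk[i + 1], sep = "\x01") %in% phrase_set) {
      out <- c(out, paste(tk[i], tk[i + 1], sep = "_"))
      i <- i + 2L
    } else {
      out <- c(out, tk[i])
      i <- i + 1L
    }
  }
  out
}

#' Apply a phrase model to token documents
#'
#' Greedy left-to-right, non-overlapping merge of adjacent pairs stored in
#' the model; when two candidate merges overlap the leftmost wins. Never
#' increases the token count.
#'
#' @param model A `phrase_model` from [fit_phrases()].
#' @param docs A token-document tibble.
#' @return The transformed token-document tibble.
#' @export
apply_phrases <- function(model, docs) {
  stopifnot(inherits(model, "phrase_model"))
  for (pass in model$passes) {
    phrase_set <- paste(pass$a, pass$b, sep = "\x01")
    docs$tokens <- lapply(docs$tokens, merge_pass, phrase_set = phrase_set)
  }
  docs
}

#' Build a vocabulary with document-frequency pruning
#'
#' Keeps terms with `min_df <= df` and `df / M <= max_df_frac`; ids are
#' assigned in lexicographic (C-locale) term order, so vocabulary
#' construction is deterministic.
#'
#' @param docs A token-document tibble.
#' @param min_df Minimum document frequency (default 1).
#' @param max_df_frac Maximum fraction of documents a term may appear in
#'   (default 1.0 = no upper pruning).
#' @return A `vocabulary` tibble with columns `term`, `id` (1..V), `df`, and
#'   attributes `V` and `M`.
#' @export
build_vocabulary <- function(docs, min_df = 1, max_df_frac = 1.0) {
  M <- nrow(docs)
  df_tab <- table(unlist(lapply(docs$tokens, unique), use.names = FALSE))
  terms <- names(df_tab)
  dfv <- as.integer(df_tab)
  keep <- dfv >= min_df & dfv / M <= max_df_frac
  terms <- terms[keep]; dfv <- dfv[keep]
  if (length(terms) == 0) {
    tt_abort(sprintf(
      "build_vocabulary: no terms survive pruning (min_df = %d, max_df_frac = %.3f over %d docs)",
      min_df, max_df_frac, M))
  }
  ord <- order(terms, method = "radix")
  vocab <- tibble::tibble(term = terms[ord], id = seq_along(ord),
                          df = dfv[ord])
  attr(vocab, "V") <- nrow(vocab)
  attr(vocab, "M") <- M
  class(vocab) <- c("vocabulary", class(vocab))
  vocab
}

#' Write / read a vocabulary as CSV
#'
#' @param vocab A `vocabulary` tibble.
#' @param path CSV path (columns `term`, `id`, `df`).
#' @return `path` invisibly, or the vocabulary for the reader.
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_csv(tibble::as_tibble(vocab[, c("term", "id", "df")]), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    term = readr::col_character(), id = readr::col_integer(),
    df = readr::col_integer()), progress = FALSE)
  vocab <- tibble::as_tibble(df[order(df$id), ])
  attr(vocab, "V") <- nrow(vocab)
  attr(vocab, "M") <- max(vocab$df)
  class(vocab) <- c("vocabulary", class(vocab))
  vocab
}

#' Convert token documents to bag-of-words form
#'
#' Maps tokens to vocabulary ids, dropping out-of-vocabulary tokens, and
#' counts occurrences per document. The result is a tidy (doc, term, count)
#' table; documents with no in-vocabulary tokens have no rows but stay in the
#' document index.
#'
#' @param docs A token-document tibble.
#' @param vocab A `vocabulary` from [build_vocabulary()].
#' @return A `bow` tibble with columns `id`, `term_id`, `count` and
#'   attributes `doc_ids` (all document ids in order) and `vocab`.
#' @export
to_bow <- function(docs, vocab) {
  id_of <- setNames(vocab$id, vocab$term)
  rows <- lapply(seq_len(nrow(docs)), function(i) {
    ids <- id_of[docs$tokens[[i]]]
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0) return(NULL)
    cnt <- table(ids)
    tibble::tibble(id = docs$id[i],
                   term_id = as.integer(names(cnt)),
                   count = as.integer(cnt))
  })
  bow <- dplyr::bind_rows(rows)
  if (nrow(bow) == 0) {
    bow <- tibble::tibble(id = character(), term_id = integer(),
                          count = integer())
  }
  attr(bow, "doc_ids") <- docs$id
  attr(bow, "vocab") <- vocab
  class(bow) <- c("bow", class(bow))
  bow
}

# docs x V sparse count matrix from a bow table (rows follow attr doc_ids)
bow_matrix <- function(bow) {
  doc_ids <- attr(bow, "doc_ids")
  vocab <- attr(bow, "vocab")
  V <- attr(vocab, "V")
  i <- match(bow$id, doc_ids)
  Matrix::sparseMatrix(i = i, j = bow$term_id, x = as.numeric(bow$count),
                       dims = c(length(doc_ids), V),
                       dimnames = list(doc_ids, vocab$term))
}
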