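test_that("tokenize_text applies the declared cleaning rules", {
  expect_equal(tokenize_text("Vaccines WORK! https://t.co/x @who #hope")[[1]],
               c("vaccines", "work", "hope"))
  expect_equal(tokenize_text("")[[1]], character())
  # hyphens split; digits kept as separate tokens
  expect_equal(tokenize_text("COVID-19 covid-19")[[1]],
               c("covid", "19", "covid", "19"))
  # stopwords removed, configurable
  expect_equal(tokenize_text("the virus is spreading")[[1]],
               c("virus", "spreading"))
  expect_equal(tokenize_text("the virus", stopwords = character())[[1]],
               c("the", "virus"))
  # urls with www, mentions with underscores
  expect_equal(tokenize_text("see www.who.int @health_org masks now")[[1]],
               c("see", "masks", "now"))
})

test_that("tokenize_text is idempotent on its own space-joined output", {
  texts <- c("Vaccines WORK! https://t.co/x @who #hope",
             "COVID-19 cases RISING... stay safe @cdc",
             "#lockdown #masks 100% effective?")
  for (tx in texts) {
    once <- tokenize_text(tx)[[1]]
    again <- tokenize_text(paste(once, collapse = " "))[[1]]
    expect_equal(again, once)
  }
})

test_that("lemmatization substitutes lemmas and filters by part of speech", {
  lex <- tibble::tibble(
    surface = c("vaccinated", "quickly", "masks"),
    lemma = c("vaccinate", "quickly", "mask"),
    pos = c("verb", "adverb", "noun"))
  docs <- toy_docs(list(c("vaccinated", "quickly"), c("unknownword")))
  out <- lemmatize_tokens(docs, lex)
  expect_equal(out$tokens[[1]], "vaccinate")   # adverb dropped
  expect_equal(out$tokens[[2]], "unknownword") # identity fallback, kept as noun
  # filter disabled: only substitution happens
  all_pos <- lemmatize_tokens(docs, lex,
                              pos_keep = c("noun", "verb", "adjective",
                                           "adverb", "other"))
  expect_equal(all_pos$tokens[[1]], c("vaccinate", "quickly"))
})

test_that("phrase scores follow the counting formula", {
  # 4 docs; "social distancing" adjacent in all of them
  docs <- toy_docs(list(c("social", "distancing", "works"),
                        c("try", "social", "distancing"),
                        c("social", "distancing", "again"),
                        c("more", "social", "distancing")))
  model <- fit_phrases(docs, min_count = 1, threshold = 1, order = "bigram")
  pass <- model$passes[[1]]
  row <- pass[pass$a == "social" & pass$b == "distancing", ]
  expect_equal(nrow(row), 1)
  # score = (count(a,b) - min_count) * V / (count(a) count(b)); V = 6 distinct
  expect_equal(row$score, (4 - 1) * 6 / 16)
  out <- apply_phrases(model, docs)
  expect_true(all(vapply(out$tokens, function(tk)
    "social_distancing" %in% tk, logical(1))))

  # a pair occurring once with min_count 5 scores <= 0: not a phrase
  rare <- toy_docs(list(c("one", "off"), c("one", "thing"), c("other", "off")))
  m2 <- fit_phrases(rare, min_count = 5, threshold = 1)
  expect_equal(nrow(m2$passes[[1]]), 0)

  expect_error(fit_phrases(docs, min_count = 0), "min_count")
  expect_error(fit_phrases(docs, threshold = 0), "threshold")
})

test_that("trigram detection is a second pass over the bigram corpus", {
  docs <- toy_docs(lapply(1:5, function(i)
    c("stay", "home", "safe", paste0("filler", i))))
  tri <- fit_phrases(docs, min_count = 1, threshold = 1, order = "trigram")
  expect_length(tri$passes, 2)
  out <- apply_phrases(tri, docs)
  expect_true(all(vapply(out$tokens, function(tk)
    "stay_home_safe" %in% tk, logical(1))))
})

test_that("apply_phrases merges greedily left to right without overlap", {
  model <- structure(list(order = "bigram", min_count = 1, threshold = 1,
                          passes = list(tibble::tibble(
                            a = c("a", "b"), b = c("b", "c"),
                            score = c(5, 5)))),
                     class = "phrase_model")
  docs <- toy_docs(list(c("a", "b", "c"), c("x", "a", "b"), c("c", "b")))
  out <- apply_phrases(model, docs)
  expect_equal(out$tokens[[1]], c("a_b", "c"))  # leftmost wins
  expect_equal(out$tokens[[2]], c("x", "a_b"))
  expect_equal(out$tokens[[3]], c("c", "b"))    # no adjacent pair

  # identity when the model holds no phrases
  empty <- structure(list(order = "bigram", min_count = 1, threshold = 1,
                          passes = list(tibble::tibble(
                            a = character(), b = character(),
                            score = numeric()))), class = "phrase_model")
  expect_equal(apply_phrases(empty, docs)$tokens, docs$tokens)

  # token count never increases; characters preserved modulo underscores
  for (i in seq_len(nrow(docs))) {
    expect_lte(length(out$tokens[[i]]), length(docs$tokens[[i]]))
    expect_equal(gsub("_", "", paste(out$tokens[[i]], collapse = "")),
                 paste(docs$tokens[[i]], collapse = ""))
  }
})

test_that("vocabulary pruning and ordering are deterministic", {
  docs <- toy_docs(list(c("b", "a", "common"), c("a", "common"),
                        c("common", "zed")))
  vocab <- build_vocabulary(docs, min_df = 1, max_df_frac = 0.9)
  expect_false("common" %in% vocab$term)  # df/M = 1 > 0.9
  expect_equal(vocab$term, c("a", "b", "zed"))  # lexicographic ids
  expect_equal(vocab$id, 1:3)

  vocab2 <- build_vocabulary(docs, min_df = 2)
  expect_equal(vocab2$term, c("a", "common"))

  empty <- toy_docs(list(c("x"), c("y")))
  expect_error(build_vocabulary(empty, min_df = 3), "no terms survive")
})

test_that("bag-of-words counts are consistent and drop OOV tokens", {
  vocab <- toy_vocab(c("a", "b"))
  docs <- toy_docs(list(c("a", "b", "a"), c("zzz"), c("a", "b")))
  bow <- to_bow(docs, vocab)
  d1 <- bow[bow$id == "d1", ]
  expect_equal(d1$count[d1$term_id == 1], 2L)
  expect_equal(d1$count[d1$term_id == 2], 1L)
  expect_equal(sum(d1$count), 3)
  expect_false("d2" %in% bow$id)            # all-OOV doc has no rows
  expect_equal(attr(bow, "doc_ids"), docs$id)  # but stays in the index

  # N_d equals the in-vocabulary token count on random documents
  set.seed(5)
  vocab2 <- toy_vocab(paste0("w", 1:8))
  rand_docs <- toy_docs(lapply(1:20, function(i)
    sample(c(paste0("w", 1:8), "oov1", "oov2"), sample(1:12, 1),
           replace = TRUE)))
  bow2 <- to_bow(rand_docs, vocab2)
  for (i in seq_len(nrow(rand_docs))) {
    in_vocab <- sum(rand_docs$tokens[[i]] %in% vocab2$term)
    expect_equal(sum(bow2$count[bow2$id == rand_docs$id[i]]), in_vocab)
  }
})
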