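test_that("disjoint vocabularies force topic separation", {
  # two long documents over disjoint word sets: each fitted topic must put
  # >90% of its mass on one block
  docs <- toy_docs(list(rep(c("apple", "pear", "plum"), 30),
                        rep(c("xray", "yak", "zebu"), 30)))
  vocab <- build_vocabulary(docs)
  bow <- to_bow(docs, vocab)
  m <- fit_lda(bow, K = 2, sweeps = 200, burn_in = 50, seed = 3)
  block1 <- match(c("apple", "pear", "plum"), m$vocab)
  block2 <- match(c("xray", "yak", "zebu"), m$vocab)
  mass1 <- rowSums(m$phi[, block1])
  mass2 <- rowSums(m$phi[, block2])
  expect_true((mass1[1] > 0.9 && mass2[2] > 0.9) ||
                (mass1[2] > 0.9 && mass2[1] > 0.9))
})

test_that("fit_lda validates its preconditions", {
  docs <- toy_docs(list(c("a", "b"), c("b", "c")))
  bow <- to_bow(docs, build_vocabulary(docs))
  expect_error(fit_lda(bow, K = 1), "K must be >= 2")
  expect_error(fit_lda(bow, K = 5), "smaller than K")
  expect_error(fit_lda(bow, K = 2, alpha = 0), "alpha")
})

test_that("count statistics are conserved and rows normalize", {
  set.seed(8)
  docs <- toy_docs(lapply(1:30, function(i)
    sample(paste0("w", 1:15), sample(5:20, 1), replace = TRUE)))
  bow <- to_bow(docs, build_vocabulary(docs))
  total_tokens <- sum(bow$count)
  for (est in c("final", "mean")) {
    m <- fit_lda(bow, K = 3, sweeps = 60, burn_in = 20, estimate = est,
                 seed = 4)
    expect_equal(sum(m$doc_topic_counts), total_tokens)
    expect_equal(sum(m$topic_word_counts), total_tokens)
    expect_equal(unname(rowSums(m$topic_word_counts)),
                 as.vector(m$topic_totals))
    expect_equal(rowSums(m$phi), rep(1, 3), tolerance = 1e-9)
    expect_equal(unname(rowSums(m$theta)), rep(1, nrow(docs)),
                 tolerance = 1e-9)
  }
})

test_that("fitting is bit-identical under a fixed seed", {
  set.seed(1)
  docs <- toy_docs(lapply(1:20, function(i)
    sample(paste0("w", 1:12), 10, replace = TRUE)))
  bow <- to_bow(docs, build_vocabulary(docs))
  m1 <- fit_lda(bow, K = 3, sweeps = 50, burn_in = 10, seed = 42)
  m2 <- fit_lda(bow, K = 3, sweeps = 50, burn_in = 10, seed = 42)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$assignments, m2$assignments)
  m3 <- fit_lda(bow, K = 3, sweeps = 50, burn_in = 10, seed = 43)
  expect_false(identical(m1$assignments, m3$assignments))
})

test_that("infer_theta folds in held-out documents", {
  docs <- toy_docs(list(rep(c("apple", "pear"), 30), rep(c("yak", "zebu"), 30)))
  vocab <- build_vocabulary(docs)
  bow <- to_bow(docs, vocab)
  m <- fit_lda(bow, K = 2, sweeps = 150, burn_in = 50, seed = 5)
  apple_topic <- which.max(m$phi[, match("apple", m$vocab)])
  th <- infer_theta(m, c("apple", "pear", "apple"), sweeps = 80, seed = 6)
  expect_equal(which.max(th), apple_topic)
  expect_equal(sum(th), 1, tolerance = 1e-12)

  empty <- infer_theta(m, character())
  expect_equal(as.numeric(empty), c(0.5, 0.5))
  expect_true(attr(empty, "empty"))

  set.seed(9)
  for (i in 1:5) {
    th_i <- infer_theta(m, sample(m$vocab, 6, replace = TRUE), sweeps = 20)
    expect_equal(sum(th_i), 1, tolerance = 1e-12)
  }
})

test_that("top_words orders by probability with id tie-breaks", {
  vocab <- toy_vocab(c("aa", "bb", "cc", "dd"))
  phi <- rbind(c(0.4, 0.3, 0.2, 0.1),
               c(0.25, 0.25, 0.25, 0.25))   # all tied
  m <- toy_lda_model(phi, vocab)
  tw <- top_words(m, topics = 1, n = 3)
  expect_equal(tw$term, c("aa", "bb", "cc"))
  expect_true(all(diff(tw$probability) <= 0))
  # ties resolve by ascending term id
  tied <- top_words(m, topics = 2, n = 4)
  expect_equal(tied$term, c("aa", "bb", "cc", "dd"))
  expect_equal(nrow(top_words(m, topics = 1, n = 0)), 0)
  # n beyond V returns V terms
  expect_equal(nrow(top_words(m, topics = 1, n = 10)), 4)
})

test_that("model serialization round-trips phi and metadata", {
  docs <- toy_docs(lapply(1:10, function(i)
    sample(paste0("w", 1:8), 6, replace = TRUE)))
  bow <- to_bow(docs, build_vocabulary(docs))
  m <- fit_lda(bow, K = 2, sweeps = 30, burn_in = 5, seed = 2)
  dir <- withr::local_tempdir()
  write_lda(m, dir)
  back <- read_lda(dir)
  expect_equal(back$phi, m$phi, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$K, m$K)
  expect_equal(back$vocab, m$vocab)
})

test_that("coherence sweep selects the generating topic count", {
  # 10 seeded replicates of a K_true = 5 corpus; the sweep's argmax must hit
  # K = 5 in at least 80% of them
  hits <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(K_true = 5, V = 200, D = 400, alpha = 0.05,
                            beta = 0.01, doc_length_lambda = 15,
                            seed = 500 + r, p_pos = 0, p_neg = 0,
                            hashtag_max = 0)
    b <- sample_corpus(cfg)
    sweep <- select_num_topics(b$tokens, c(2, 5, 10), variants = "unigram",
                               sweeps = 120, burn_in = 40, window = 20,
                               top_n = 8, seed = 900 + r)
    expect_equal(nrow(sweep), 3)   # one row per candidate K
    hits <- hits + (sweep$K[attr(sweep, "best")] == 5)
  }
  expect_gte(hits, 0.8 * n_rep)
})

test_that("sweep reports bigram and trigram variants side by side", {
  cfg <- generator_config(K_true = 3, V = 80, D = 120, alpha = 0.05,
                          doc_length_lambda = 12, seed = 31, p_pos = 0,
                          p_neg = 0, hashtag_max = 0,
                          planted_phrases = "stay home",
                          planted_prob = 0.6)
  b <- sample_corpus(cfg)
  sweep <- select_num_topics(b$tokens, c(2, 3), variants = c("bigram",
                                                             "trigram"),
                             sweeps = 60, burn_in = 20, window = 15,
                             top_n = 5, min_count = 2, threshold = 1,
                             seed = 77)
  expect_equal(nrow(sweep), 4)
  expect_setequal(unique(sweep$variant), c("bigram", "trigram"))
  expect_true(all(is.finite(sweep$coherence)))
})
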