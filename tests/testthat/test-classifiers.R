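grad_check_setup <- function(arch, seed = 4) {
  set.seed(seed)
  V <- 12; dim <- 5; K <- 3; n <- 5; L <- 6
  vocab <- toy_vocab(sprintf("t%02d", 1:V))
  E <- build_embeddings(vocab, dim = dim, seed = 3)
  docs <- toy_docs(lapply(1:n, function(i)
    sample(vocab$term, sample(3:L, 1), replace = TRUE)))
  batch <- encode_batch(docs, sample(1:K, n, replace = TRUE), vocab,
                        max_len = L, n_classes = K)
  spec <- neural_spec(arch, E, hidden = c(4), filter_count = 3,
                      kernel_size = 2, hidden_units = 3, dense_units = 4,
                      dropout = 0)
  model <- build_model(spec, n_classes = K, seed = 5)
  # jitter away from the zero-bias ReLU/max-pool kinks where the loss is
  # non-differentiable
  model$params <- lapply(model$params, function(p) p + 0.3 * rnorm(length(p)))
  list(model = model, batch = batch)
}

test_that("analytic gradients match finite differences for every architecture", {
  ns <- asNamespace("tweettopics")
  for (arch in c("ffnn", "cnn", "bilstm")) {
    su <- grad_check_setup(arch)
    fwd <- ns$model_forward(su$model, su$batch, training = FALSE)
    dlogits <- (fwd$probs - su$batch$y) / nrow(su$batch$y)
    grads <- ns$model_backward(su$model, fwd$cache, dlogits)
    eps <- 1e-5
    for (nm in names(su$model$params)) {
      p <- su$model$params[[nm]]
      idx <- sample(length(p), min(8, length(p)))
      for (ii in idx) {
        bump <- function(h) {
          m <- su$model
          m$params[[nm]][ii] <- p[ii] + h
          ns$bce_loss(ns$model_forward(m, su$batch)$probs, su$batch$y)
        }
        num <- (bump(eps) - bump(-eps)) / (2 * eps)
        expect_equal(grads[[nm]][ii], num, tolerance = 1e-6,
                     label = paste(arch, nm, ii))
      }
    }
  }
})

test_that("parameter counts follow the declared layer shapes", {
  vocab <- toy_vocab(sprintf("t%03d", 1:20))
  E <- build_embeddings(vocab, dim = 300, seed = 1)
  spec <- neural_spec("ffnn", E, hidden = c(64))
  m <- build_model(spec, n_classes = 10, seed = 1)
  expect_equal(m$n_parameters, 300 * 64 + 64 + 64 * 10 + 10)  # 19,914
})

test_that("builds are deterministic and spec validation rejects bad configs", {
  vocab <- toy_vocab(letters[1:6])
  E <- build_embeddings(vocab, dim = 8, seed = 2)
  spec <- neural_spec("cnn", E, filter_count = 4, kernel_size = 2,
                      dense_units = 4)
  m1 <- build_model(spec, n_classes = 3, seed = 9)
  m2 <- build_model(spec, n_classes = 3, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(spec, n_classes = 3, seed = 10)
  expect_false(identical(m1$params, m3$params))

  expect_error(neural_spec("ffnn", E, dropout = 1), "dropout")
  expect_error(neural_spec("ffnn", E, output_units = 1), "output_units")
  expect_error(neural_spec("mlp", E))
  expect_error(build_model(neural_spec("ffnn", E), n_classes = NULL),
               "n_classes")

  # kernel wider than the padded sequence is a config error at use time
  wide <- build_model(neural_spec("cnn", E, kernel_size = 9, filter_count = 2),
                      n_classes = 2, seed = 1)
  docs <- toy_docs(list(c("a", "b")))
  b <- encode_batch(docs, 1L, vocab, max_len = 4, n_classes = 2)
  expect_error(predict(wide, b), "kernel_size")
})

test_that("epochs = 0 leaves the model untouched", {
  vocab <- toy_vocab(letters[1:6])
  E <- build_embeddings(vocab, dim = 8, seed = 2)
  m <- build_model(neural_spec("ffnn", E, hidden = c(4)), n_classes = 2,
                   seed = 3)
  docs <- toy_docs(list(c("a", "b"), c("c", "d")))
  b <- encode_batch(docs, c(1L, 2L), vocab, max_len = 4, n_classes = 2)
  out <- train_classifier(m, b, epochs = 0)
  expect_identical(out$params, m$params)
  expect_equal(nrow(out$history), 0)
})

test_that("a tiny memorizable set is overfit with non-increasing loss trend", {
  set.seed(6)
  vocab <- toy_vocab(sprintf("w%02d", 1:10))
  E <- build_embeddings(vocab, dim = 16, seed = 4)
  docs <- toy_docs(lapply(1:8, function(i)
    sample(vocab$term, 5, replace = TRUE)))
  labels <- rep(1:2, each = 4)
  b <- encode_batch(docs, labels, vocab, max_len = 6, n_classes = 2)
  m <- build_model(neural_spec("ffnn", E, hidden = c(32), dropout = 0),
                   n_classes = 2, seed = 5)
  m <- train_classifier(m, b, epochs = 150, batch_size = 8,
                        learning_rate = 0.02, seed = 7)
  h <- m$history$train_loss
  expect_lt(h[length(h)], h[1] / 2)
  expect_gte(m$history$train_accuracy[nrow(m$history)], 0.99)
})

test_that("training on linearly separable classes reaches near-perfect accuracy", {
  b <- separable_bundle(D = 300, K = 2, V = 80, seed = 29)
  vocab <- build_vocabulary(b$tokens)
  E <- small_embeddings(vocab, dim = 16)
  batch <- encode_batch(b$tokens, b$truth$topic, vocab, max_len = 30,
                        n_classes = 2)
  m <- build_model(neural_spec("ffnn", E, hidden = c(16), dropout = 0),
                   n_classes = 2, seed = 8)
  m <- train_classifier(m, batch, epochs = 30, batch_size = 32, seed = 9)
  expect_gte(tail(m$history$train_accuracy, 1), 0.99)
})

test_that("prediction takes the arg-max with smallest-index ties and sigmoid scores", {
  b <- separable_bundle(D = 60, K = 3, V = 60, seed = 33)
  vocab <- build_vocabulary(b$tokens)
  E <- small_embeddings(vocab, dim = 8)
  batch <- encode_batch(b$tokens, b$truth$topic, vocab, max_len = 20,
                        n_classes = 3)
  m <- build_model(neural_spec("ffnn", E, hidden = c(8), dropout = 0),
                   n_classes = 3, seed = 2)
  scores <- predict(m, batch, type = "prob")
  expect_equal(dim(scores), c(60, 3))
  expect_true(all(scores > 0 & scores < 1))
  # sigmoid head: score rows are NOT normalized to sum to 1
  expect_gt(max(abs(rowSums(scores) - 1)), 1e-3)
  labels <- predict(m, batch)
  expect_equal(labels, max.col(scores, ties.method = "first"))
})

test_that("seeded training is bit-reproducible", {
  b <- separable_bundle(D = 120, K = 2, V = 60, seed = 41)
  vocab <- build_vocabulary(b$tokens)
  E <- small_embeddings(vocab, dim = 8)
  batch <- encode_batch(b$tokens, b$truth$topic, vocab, max_len = 20,
                        n_classes = 2)
  run <- function() {
    m <- build_model(neural_spec("bilstm", E, hidden_units = 4,
                                 dense_units = 4, dropout = 0.3),
                     n_classes = 2, seed = 5)
    train_classifier(m, batch, epochs = 2, batch_size = 32, seed = 6)
  }
  m1 <- run(); m2 <- run()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("model containers round-trip through JSON", {
  b <- separable_bundle(D = 80, K = 2, V = 60, seed = 51)
  vocab <- build_vocabulary(b$tokens)
  E <- small_embeddings(vocab, dim = 8, seed = 3)
  batch <- encode_batch(b$tokens, b$truth$topic, vocab, max_len = 20,
                        n_classes = 2)
  m <- build_model(neural_spec("cnn", E, filter_count = 4, kernel_size = 2,
                               dense_units = 4), n_classes = 2, seed = 4)
  m <- train_classifier(m, batch, epochs = 2, batch_size = 32, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path, vocab)
  back <- read_model(path, vocab)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_equal(predict(back, batch), predict(m, batch))
})
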