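#' Specify a neural tweet classifier
#'
#' Declares one of three architectures over a shared frozen word-embedding
#' layer, all ending in a `K`-unit sigmoid head trained with binary
#' cross-entropy (the multilabel-style head; predicted score vectors are not
#' softmax-normalized):
#'
#' * `ffnn` - mask-aware mean pooling of token embeddings, then a stack of
#'   ReLU dense layers with dropout;
#' * `cnn` - 1-D convolution (ReLU) over the embedded sequence, global max
#'   pooling, then a dense + dropout block;
#' * `bilstm` - bidirectional LSTM; the two final hidden states are
#'   concatenated and passed through a dense + dropout block.
#'
#' @param arch `"ffnn"`, `"cnn"` or `"bilstm"`.
#' @param embedding An `embedding_matrix` from [build_embeddings()]; its
#'   vectors are held fixed during training.
#' @param output_units Number of sigmoid output units (default `K` is set
#'   when the first batch is seen; must be >= 2 when given).
#' @param hidden Dense layer sizes for `ffnn` (default `c(128, 64)`).
#' @param filter_count,kernel_size CNN filters (default 128) and kernel
#'   width (default 3).
#' @param hidden_units LSTM hidden units per direction (default 64).
#' @param dense_units Width of the dense block after pooling for `cnn` /
#'   `bilstm` (default 64).
#' @param dropout Dropout rate in `[0, 1)` (default 0.5).
#' @return A `neural_spec` object.
#' @export
neural_spec <- function(arch = c("ffnn", "cnn", "bilstm"), embedding,
                        output_units = NULL,
                        hidden = c(128, 64),
                        filter_count = 128, kernel_size = 3,
                        hidden_units = 64, dense_units = 64,
                        dropout = 0.5) {
  arch <- match.arg(arch)
  if (!inherits(embedding, "embedding_matrix")) {
    tt_abort("`embedding` must come from build_embeddings()")
  }
  if (dropout < 0 || dropout >= 1) tt_abort("dropout must be in [0, 1)")
  if (!is.null(output_units) && output_units < 2) {
    tt_abort("output_units must be >= 2")
  }
  structure(list(arch = arch, embedding = embedding,
                 output_units = output_units, hidden = hidden,
                 filter_count = filter_count, kernel_size = kernel_size,
                 hidden_units = hidden_units, dense_units = dense_units,
                 dropout = dropout, dim = ncol(embedding)),
            class = "neural_spec")
}

#' Build an untrained classifier from a spec
#'
#' Initializes all trainable weights (Glorot-uniform; LSTM forget-gate
#' biases start at 1) from the given seed, so two builds from the same spec
#' and seed have identical initial weights. The reported parameter count
#' covers the trainable weights (the embedding matrix is frozen).
#'
#' @param spec A [neural_spec()].
#' @param n_classes Number of output classes `K` (overrides
#'   `spec$output_units` when that is `NULL`).
#' @param seed Integer seed for weight initialization.
#' @return A `neural_model` with elements `spec`, `params`, `n_classes`,
#'   `n_parameters`, `seed`, `history` (empty until trained).
#' @export
build_model <- function(spec, n_classes = spec$output_units, seed = 1) {
  stopifnot(inherits(spec, "neural_spec"))
  if (is.null(n_classes)) tt_abort("n_classes must be given (or set output_units)")
  if (n_classes < 2) tt_abort("output_units must be >= 2")
  dim <- spec$dim
  params <- with_preserved_seed(seed, switch(
    spec$arch,
    ffnn = ffnn_init(dim, spec$hidden, n_classes),
    cnn = cnn_init(dim, spec$kernel_size, spec$filter_count,
                   spec$dense_units, n_classes),
    bilstm = bilstm_init(dim, spec$hidden_units, spec$dense_units, n_classes)
  ))
  structure(list(spec = spec, params = params,
                 n_classes = as.integer(n_classes),
                 n_parameters = sum(vapply(params, length, integer(1))),
                 seed = seed,
                 E_aug = augment_embedding(spec$embedding),
                 history = tibble::tibble(epoch = integer(),
                                          train_loss = numeric(),
                                          train_accuracy = numeric(),
                                          val_loss = numeric(),
                                          val_accuracy = numeric())),
            class = "neural_model")
}

#' @export
print.neural_model <- function(x, ...) {
  cat(sprintf("<neural_model: %s, K = %d, %d trainable parameters, %d epochs trained>\n",
              x$spec$arch, x$n_classes, x$n_parameters, nrow(x$history)))
  invisible(x)
}

model_forward <- function(model, batch, training = FALSE) {
  spec <- model$spec
  switch(spec$arch,
         ffnn = ffnn_forward(model$params, model$E_aug, batch,
                             dropout = spec$dropout, training = training),
         cnn = cnn_forward(model$params, model$E_aug, batch,
                           kernel_size = spec$kernel_size,
                           dropout = spec$dropout, training = training),
         bilstm = bilstm_forward(model$params, model$E_aug, batch,
                                 H = spec$hidden_units,
                                 dropout = spec$dropout, training = training))
}

model_backward <- function(model, cache, dlogits) {
  switch(model$spec$arch,
         ffnn = ffnn_backward(model$params, cache, dlogits),
         cnn = cnn_backward(model$params, cache, dlogits),
         bilstm = bilstm_backward(model$params, cache, dlogits))
}

eval_batch <- function(model, batch) {
  fwd <- model_forward(model, batch, training = FALSE)
  list(loss = bce_loss(fwd$probs, batch$y),
       accuracy = mean(max.col(fwd$probs, ties.method = "first") ==
                         batch$labels))
}

#' Train a neural classifier
#'
#' Mini-batch Adam on the summed per-class binary cross-entropy
#' `-sum_c [y_c log p_c + (1 - y_c) log(1 - p_c)]` against the one-hot
#' targets. Shuffling and dropout are driven by the seed, so single-threaded
#' training is bit-reproducible. Per-epoch train (and optional validation)
#' loss and accuracy are recorded in the model's `history`.
#'
#' @param model An untrained (or previously trained) `neural_model`.
#' @param train An `encoded_batch` of training data (its `y` width must
#'   match the model's output units).
#' @param val Optional validation `encoded_batch`.
#' @param epochs Number of passes over the training data (0 returns the
#'   model unchanged with empty history).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for shuffling and dropout.
#' @return The trained `neural_model` with filled `history`.
#' @export
train_classifier <- function(model, train, val = NULL, epochs = 10,
                             batch_size = 64, learning_rate = 1e-3,
                             seed = 1) {
  stopifnot(inherits(model, "neural_model"), inherits(train, "encoded_batch"))
  if (ncol(train$y) != model$n_classes) {
    tt_abort("label dimension does not match the model's output units")
  }
  if (epochs == 0) return(model)
  set.seed(seed)
  state <- adam_init(model$params)
  n <- nrow(train$ids)
  history <- model$history
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1, n)]
      mb <- batch_subset(train, idx)
      fwd <- model_forward(model, mb, training = TRUE)
      loss <- bce_loss(fwd$probs, mb$y)
      if (!is.finite(loss)) {
        tt_abort(sprintf("non-finite loss at epoch %d; reduce learning_rate",
                         epoch))
      }
      dlogits <- (fwd$probs - mb$y) / nrow(mb$y)
      grads <- model_backward(model, fwd$cache, dlogits)
      upd <- adam_step(model$params, grads, state, lr = learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    tr <- eval_batch(model, train)
    vl <- if (is.null(val)) list(loss = NA_real_, accuracy = NA_real_) else
      eval_batch(model, val)
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = epoch, train_loss = tr$loss, train_accuracy = tr$accuracy,
      val_loss = vl$loss, val_accuracy = vl$accuracy))
  }
  model$history <- history
  model
}

#' Predict classes or per-class scores
#'
#' Scores are independent per-class sigmoid outputs in `(0, 1)` (they need
#' not sum to 1); the hard label is the arg-max score with ties broken to
#' the smallest class index.
#'
#' @param object A `neural_model`.
#' @param batch An `encoded_batch`.
#' @param type `"class"` for hard integer labels, `"prob"` for the
#'   `n x K` score matrix.
#' @param ... Unused.
#' @return Integer labels or a score matrix.
#' @export
predict.neural_model <- function(object, batch, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  fwd <- model_forward(object, batch, training = FALSE)
  if (type == "prob") return(fwd$probs)
  max.col(fwd$probs, ties.method = "first")
}

#' Save / load a trained classifier
#'
#' A single JSON container holding the spec scalars, flattened weight
#' arrays with their shapes, and the training history; the embedding matrix
#' is rebuilt from its provider at load time for the hashed provider, or
#' must be re-supplied for file-backed embeddings.
#'
#' @param model A `neural_model`.
#' @param path Output JSON path.
#' @param vocab The `vocabulary` the embedding was built over.
#' @return `path` invisibly; `read_model()` returns the `neural_model`.
#' @export
write_model <- function(model, path, vocab) {
  spec <- model$spec
  payload <- list(
    arch = spec$arch, output_units = model$n_classes,
    hidden = spec$hidden, filter_count = spec$filter_count,
    kernel_size = spec$kernel_size, hidden_units = spec$hidden_units,
    dense_units = spec$dense_units, dropout = spec$dropout,
    dim = spec$dim, seed = model$seed,
    embedding_provider = attr(spec$embedding, "provider"),
    embedding_seed = attr(spec$embedding, "seed"),
    terms = vocab$term,
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), data = as.numeric(p))),
    history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path, vocab, embedding = NULL) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(embedding)) {
    embedding <- build_embeddings(vocab, provider = "hashed", dim = pl$dim,
                                  seed = pl$embedding_seed %||% 1)
  }
  spec <- neural_spec(pl$arch, embedding, output_units = pl$output_units,
                      hidden = pl$hidden, filter_count = pl$filter_count,
                      kernel_size = pl$kernel_size,
                      hidden_units = pl$hidden_units,
                      dense_units = pl$dense_units, dropout = pl$dropout)
  model <- build_model(spec, n_classes = pl$output_units, seed = pl$seed)
  for (nm in names(model$params)) {
    entry <- pl$params[[nm]]
    p <- entry$data
    if (length(entry$dim) == 2) p <- matrix(p, entry$dim[1], entry$dim[2])
    model$params[[nm]] <- p
  }
  model$history <- tibble::as_tibble(pl$history)
  model
}
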