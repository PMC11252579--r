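# deterministic 31-bit string hash (polynomial accumulator; kept in double
# precision, all intermediates < 2^53)
string_hash <- function(term) {
  bytes <- utf8ToInt(term)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

hashed_row <- function(term, dim, seed) {
  h <- (string_hash(term) + (seed %% 65521) * 65537) %% 2147483647
  v <- with_preserved_seed(as.integer(h), rnorm(dim))
  v / sqrt(sum(v^2))
}

#' Build an embedding matrix for a vocabulary
#'
#' Static per-word vectors aligned to vocabulary ids, from one of two
#' providers:
#'
#' * `"hashed"` - each row is derived from a keyed hash of the term expanded
#'   into `dim` pseudo-random values and L2-normalized. The same term always
#'   maps to the same row (for a given `seed` and `dim`), independent of the
#'   vocabulary it sits in. Fully offline and deterministic.
#' * `"file"` - vectors loaded from a word2vec text-format file (header line
#'   `"<n> <dim>"`, then `term v1 ... vdim` per line); vocabulary terms
#'   missing from the file fall back to hashed rows (count reported).
#'
#' @param vocab A `vocabulary` tibble.
#' @param provider `"hashed"` (default) or `"file"`.
#' @param dim Embedding dimension (default 300).
#' @param seed Hash key for the hashed provider.
#' @param path Path to the vector file (file provider only).
#' @return An `embedding_matrix`: a `V x dim` matrix with terms as rownames
#'   and attributes `provider` and (file provider) `n_fallback`.
#' @export
build_embeddings <- function(vocab, provider = c("hashed", "file"),
                             dim = 300, seed = 1, path = NULL) {
  provider <- match.arg(provider)
  terms <- vocab$term
  if (provider == "hashed") {
    E <- t(vapply(terms, hashed_row, numeric(dim), dim = dim, seed = seed))
    n_fallback <- 0L
  } else {
    if (is.null(path)) tt_abort("file provider requires `path`")
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    if (length(lines) < 1) tt_abort("empty vector file")
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(header) != 2 || anyNA(suppressWarnings(as.integer(header)))) {
      tt_abort("malformed vector file at line 1: expected '<count> <dim>'")
    }
    file_dim <- as.integer(header[2])
    vecs <- new.env(parent = emptyenv())
    for (i in seq_along(lines)[-1]) {
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(parts) != file_dim + 1) {
        tt_abort(sprintf("malformed vector file at line %d: %d fields, expected %d",
                         i, length(parts), file_dim + 1))
      }
      v <- suppressWarnings(as.numeric(parts[-1]))
      if (anyNA(v)) {
        tt_abort(sprintf("malformed vector file at line %d: non-numeric value", i))
      }
      assign(parts[1], v, envir = vecs)
    }
    dim <- file_dim
    n_fallback <- 0L
    E <- matrix(0, length(terms), dim)
    for (i in seq_along(terms)) {
      if (exists(terms[i], envir = vecs, inherits = FALSE)) {
        E[i, ] <- get(terms[i], envir = vecs)
      } else {
        E[i, ] <- hashed_row(terms[i], dim, seed)
        n_fallback <- n_fallback + 1L
      }
    }
    if (n_fallback > 0) {
      tt_inform("build_embeddings: ", n_fallback,
                " vocabulary terms missing from file; hashed fallback used")
    }
  }
  rownames(E) <- terms
  if (!all(is.finite(E))) tt_abort("non-finite embedding values")
  structure(E, provider = provider, n_fallback = n_fallback, seed = seed,
            class = c("embedding_matrix", class(E)))
}

#' Encode token documents into fixed-length padded batches
#'
#' Maps tokens to vocabulary ids, right-pads with the pad id 0 up to
#' `max_len` (truncating longer documents on the right), and one-hot encodes
#' the class labels. Out-of-vocabulary tokens are dropped before padding.
#'
#' @param docs A token-document tibble.
#' @param labels Integer class labels in `1..n_classes`, one per document
#'   (`NA` rows are dropped with a message).
#' @param vocab A `vocabulary` tibble.
#' @param max_len Maximum sequence length (default 50, ample for tweets).
#' @param n_classes Number of classes `K` (default `max(labels)`).
#' @return An `encoded_batch`: list with `ids` (n x max_len integer matrix,
#'   0 = pad), `mask` (n x max_len, 1 on non-pad positions), `y` (n x K
#'   one-hot matrix), `labels`, `doc_ids`, `max_len`, `n_classes`.
#' @export
encode_batch <- function(docs, labels, vocab, max_len = 50,
                         n_classes = max(labels, na.rm = TRUE)) {
  if (max_len < 1) tt_abort("max_len must be >= 1")
  stopifnot(nrow(docs) == length(labels))
  keep <- !is.na(labels)
  if (any(!keep)) {
    tt_inform("encode_batch: dropping ", sum(!keep), " unlabeled documents")
    docs <- docs[keep, ]; labels <- labels[keep]
  }
  id_of <- setNames(vocab$id, vocab$term)
  n <- nrow(docs)
  ids <- matrix(0L, n, max_len)
  for (i in seq_len(n)) {
    tok_ids <- id_of[docs$tokens[[i]]]
    tok_ids <- as.integer(tok_ids[!is.na(tok_ids)])
    L <- min(length(tok_ids), max_len)
    if (L > 0) ids[i, seq_len(L)] <- tok_ids[seq_len(L)]
  }
  mask <- (ids != 0L) * 1
  y <- matrix(0, n, n_classes)
  y[cbind(seq_len(n), labels)] <- 1
  structure(list(ids = ids, mask = mask, y = y, labels = as.integer(labels),
                 doc_ids = docs$id, max_len = max_len,
                 n_classes = as.integer(n_classes)),
            class = "encoded_batch")
}

#' Decode an encoded batch back to id sequences
#'
#' Drops pads; together with [encode_batch()] this recovers each document's
#' in-vocabulary id sequence up to truncation.
#'
#' @param batch An `encoded_batch`.
#' @return A list of integer id vectors.
#' @export
decode_batch <- function(batch) {
  lapply(seq_len(nrow(batch$ids)), function(i) {
    row <- batch$ids[i, ]
    as.integer(row[row != 0L])
  })
}

# subset an encoded batch by row indices
batch_subset <- function(batch, idx) {
  structure(list(ids = batch$ids[idx, , drop = FALSE],
                 mask = batch$mask[idx, , drop = FALSE],
                 y = batch$y[idx, , drop = FALSE],
                 labels = batch$labels[idx],
                 doc_ids = batch$doc_ids[idx],
                 max_len = batch$max_len, n_classes = batch$n_classes),
            class = "encoded_batch")
}
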