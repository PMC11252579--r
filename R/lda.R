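#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Fits the standard latent Dirichlet allocation model: each document `d`
#' draws topic proportions `theta_d ~ Dirichlet(alpha)`, each topic `k` a
#' word distribution `phi_k ~ Dirichlet(beta)`, and every token a topic then
#' a word. Inference integrates `theta` and `phi` out and resamples each
#' token's topic assignment from its full conditional
#' `P(z = k | .) \propto (n_dk + alpha) (n_kw + beta) / (n_k + V beta)`.
#' Point estimates are `phi_kw = (n_kw + beta) / (n_k + V beta)` and
#' `theta_dk = (n_dk + alpha) / (N_d + K alpha)`, from either the final
#' sweep's counts or the post-burn-in mean counts.
#'
#' Runs are bit-identical for a fixed `seed`.
#'
#' @param bow A `bow` table from [to_bow()].
#' @param K Number of topics (>= 2).
#' @param alpha Symmetric document-topic concentration (default `1/K`).
#' @param beta Symmetric topic-word concentration (default 0.01).
#' @param sweeps Total Gibbs sweeps (default 500).
#' @param burn_in Sweeps discarded before averaging when
#'   `estimate = "mean"` (default 100).
#' @param estimate `"final"` (counts of the last sweep, the default) or
#'   `"mean"` (average counts after burn-in).
#' @param restarts Number of independently initialized chains; the chain
#'   with the highest collapsed log joint probability `log P(w, z)` is
#'   kept (default 1). Restarting guards against the occasional local mode
#'   in which two true topics merge; each chain's seed derives
#'   deterministically from `seed`.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return An object of class `lda_model` with elements `K`, `V`, `alpha`,
#'   `beta`, `phi` (K x V), `theta` (M x K), `topic_word_counts`,
#'   `topic_totals`, `doc_topic_counts`, `assignments`, `vocab`, `doc_ids`,
#'   `sweeps`, `burn_in`, `seed`.
#' @export
fit_lda <- function(bow, K, alpha = 1 / K, beta = 0.01, sweeps = 500,
                    burn_in = 100, estimate = c("final", "mean"),
                    restarts = 1, seed = NULL) {
  estimate <- match.arg(estimate)
  if (restarts > 1) {
    if (is.null(seed)) tt_abort("fit_lda: restarts > 1 requires a seed")
    fits <- lapply(seq_len(restarts), function(r) {
      fit_lda(bow, K = K, alpha = alpha, beta = beta, sweeps = sweeps,
              burn_in = burn_in, estimate = estimate, restarts = 1,
              seed = (seed + 777767 * (r - 1)) %% 2147483647)
    })
    scores <- vapply(fits, `[[`, numeric(1), "log_joint")
    return(fits[[which.max(scores)]])
  }
  vocab <- attr(bow, "vocab")
  doc_ids <- attr(bow, "doc_ids")
  V <- attr(vocab, "V")
  if (K < 2) tt_abort("fit_lda: K must be >= 2")
  if (V < K) tt_abort("fit_lda: vocabulary smaller than K")
  if (alpha <= 0 || beta <= 0) tt_abort("fit_lda: alpha and beta must be > 0")
  if (nrow(bow) == 0) tt_abort("fit_lda: empty corpus (no in-vocabulary tokens)")
  M <- length(doc_ids)

  ord <- order(match(bow$id, doc_ids), bow$term_id)
  doc_tok <- rep(match(bow$id, doc_ids)[ord] - 1L, bow$count[ord])
  word_tok <- rep(bow$term_id[ord] - 1L, bow$count[ord])

  if (!is.null(seed)) set.seed(seed)
  fit <- .gibbs_lda_fit(doc_tok, word_tok, M, V, K, alpha, beta,
                        as.integer(sweeps), as.integer(burn_in),
                        estimate == "mean")

  est_kw <- fit$est_kw; est_k <- fit$est_k; est_dk <- fit$est_dk
  phi <- (est_kw + beta) / (est_k + V * beta)
  N_d <- rowSums(fit$n_dk)
  theta <- (est_dk + alpha) / (N_d + K * alpha)
  dimnames(phi) <- list(NULL, vocab$term)
  rownames(theta) <- doc_ids

  # collapsed log joint log P(w, z) of the final state, used to compare
  # independently restarted chains
  log_joint <-
    K * (lgamma(V * beta) - V * lgamma(beta)) +
    sum(lgamma(fit$n_kw + beta)) - sum(lgamma(fit$n_k + V * beta)) +
    M * (lgamma(K * alpha) - K * lgamma(alpha)) +
    sum(lgamma(fit$n_dk + alpha)) - sum(lgamma(N_d + K * alpha))

  structure(list(log_joint = log_joint,
                 K = K, V = V, alpha = alpha, beta = beta,
                 phi = phi, theta = theta,
                 topic_word_counts = fit$n_kw, topic_totals = fit$n_k,
                 doc_topic_counts = fit$n_dk, assignments = fit$z,
                 vocab = vocab$term, doc_ids = doc_ids,
                 sweeps = sweeps, burn_in = burn_in, estimate = estimate,
                 seed = seed),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: K = %d topics, V = %d terms, %d docs, %d sweeps>\n",
              x$K, x$V, length(x$doc_ids), x$sweeps))
  invisible(x)
}

#' Infer topic proportions for a new document
#'
#' Fold-in Gibbs inference: the fitted topic-word counts are held fixed and
#' only the document's own topic assignments are resampled. An empty
#' document yields the uniform distribution, flagged via attribute
#' `"empty"`.
#'
#' @param model A fitted `lda_model`.
#' @param doc Either an integer vector of vocabulary term ids (with
#'   repetitions) or a character vector of terms.
#' @param sweeps Gibbs sweeps for the fold-in (default 50).
#' @param seed Optional integer seed.
#' @return A length-`K` probability vector summing to 1.
#' @export
infer_theta <- function(model, doc, sweeps = 50, seed = NULL) {
  stopifnot(inherits(model, "lda_model"))
  if (is.character(doc)) {
    doc <- match(doc, model$vocab)
    doc <- doc[!is.na(doc)]
  }
  doc <- as.integer(doc)
  if (length(doc) == 0) {
    out <- rep(1 / model$K, model$K)
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (any(doc < 1 | doc > model$V)) tt_abort("infer_theta: term id out of range")
  if (!is.null(seed)) set.seed(seed)
  .gibbs_lda_infer(doc - 1L, model$topic_word_counts * 1.0,
                   model$topic_totals * 1.0, model$alpha, model$beta,
                   as.integer(sweeps))
}

#' Top words of fitted topics
#'
#' @param model A fitted `lda_model`.
#' @param topics Topic ids to report (default all).
#' @param n Number of terms per topic; ties in probability break by
#'   ascending term id. `n` larger than `V` returns all `V` terms.
#' @return A tibble with columns `topic`, `term`, `probability`, `rank`,
#'   probabilities non-increasing within each topic.
#' @export
top_words <- function(model, topics = seq_len(model$K), n = 10) {
  stopifnot(inherits(model, "lda_model"))
  if (any(topics < 1 | topics > model$K)) tt_abort("topic id out of range")
  n <- min(n, model$V)
  rows <- lapply(topics, function(k) {
    p <- model$phi[k, ]
    ord <- order(-p, seq_along(p))[seq_len(n)]
    if (n == 0) return(NULL)
    tibble::tibble(topic = k, term = model$vocab[ord],
                   probability = unname(p[ord]), rank = seq_len(n))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(topic = integer(), term = character(),
                          probability = numeric(), rank = integer())
  }
  out
}

#' Serialize / load an LDA model
#'
#' The model is written as a JSON header (scalars, vocabulary) plus CSV
#' matrices for `phi` and `theta`, all plain text.
#'
#' @param model A fitted `lda_model`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly, or the reloaded `lda_model`.
#' @export
write_lda <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- model[c("K", "V", "alpha", "beta", "sweeps", "burn_in",
                    "estimate", "seed", "vocab", "doc_ids")]
  jsonlite::write_json(header, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(model$phi, file.path(dir, "phi.csv"), row.names = FALSE)
  utils::write.csv(model$theta, file.path(dir, "theta.csv"), row.names = FALSE)
  utils::write.csv(model$topic_word_counts, file.path(dir, "topic_word_counts.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_lda
#' @export
read_lda <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"),
                                simplifyVector = TRUE)
  phi <- as.matrix(utils::read.csv(file.path(dir, "phi.csv"), check.names = FALSE))
  theta <- as.matrix(utils::read.csv(file.path(dir, "theta.csv"), check.names = FALSE))
  nkw <- as.matrix(utils::read.csv(file.path(dir, "topic_word_counts.csv"),
                                   check.names = FALSE))
  dimnames(nkw) <- NULL
  rownames(theta) <- header$doc_ids
  structure(list(K = header$K, V = header$V, alpha = header$alpha,
                 beta = header$beta, phi = phi, theta = theta,
                 topic_word_counts = nkw, topic_totals = rowSums(nkw),
                 doc_topic_counts = NULL, assignments = NULL,
                 vocab = header$vocab, doc_ids = header$doc_ids,
                 sweeps = header$sweeps, burn_in = header$burn_in,
                 estimate = header$estimate, seed = header$seed),
            class = "lda_model")
}
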