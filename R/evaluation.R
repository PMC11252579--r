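#' Confusion matrix for multiclass predictions
#'
#' `C x C` integer matrix with rows indexing the true class and columns the
#' predicted class: `M[i, j]` counts items of true class `i` predicted as
#' `j`. Per-class one-vs-rest counts follow as `TP_c = M[c, c]`,
#' `FP_c = colsum_c - TP_c`, `FN_c = rowsum_c - TP_c`,
#' `TN_c = total - TP_c - FP_c - FN_c`.
#'
#' @param y_true,y_pred Integer class labels in `1..n_classes`.
#' @param n_classes Number of classes `C`.
#' @return A `confusion_matrix` (integer matrix with class attribute).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) > 0 &&
      (min(y_true, y_pred) < 1 || max(y_true, y_pred) > n_classes)) {
    tt_abort("labels out of range 1..n_classes")
  }
  M <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = seq_len(n_classes),
                              pred = seq_len(n_classes)))
  for (i in seq_along(y_true)) {
    M[y_true[i], y_pred[i]] <- M[y_true[i], y_pred[i]] + 1L
  }
  structure(M, class = c("confusion_matrix", "matrix", "array"))
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall, F1, accuracy, FPR and specificity from the
#' one-vs-rest decomposition, plus macro (unweighted mean over classes) and
#' micro (pooled TP/FP/FN/TN) aggregates. Divisions by zero yield 0 and are
#' flagged. For single-label multiclass data micro-F1 coincides with
#' accuracy.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metric_report`: list with `per_class` (tibble), `macro`,
#'   `micro` (one-row tibbles), and overall `accuracy`.
#' @export
eval_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  C <- nrow(cm)
  total <- sum(cm)
  tp <- unname(diag(cm))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- total - tp - fp - fn
  class_metrics <- function(tp, fp, fn, tn) {
    precision <- safe_div(tp, tp + fp)
    recall <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * precision * recall, precision + recall)
    accuracy <- safe_div(tp + tn, tp + tn + fp + fn)
    fpr <- safe_div(fp, fp + tn)
    tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = precision, recall = recall, f1 = f1,
                   accuracy = accuracy, fpr = fpr, specificity = 1 - fpr,
                   zero_division = (tp + fp == 0) | (tp + fn == 0))
  }
  per_class <- dplyr::bind_cols(tibble::tibble(class = seq_len(C)),
                                class_metrics(tp, fp, fn, tn))
  macro <- per_class |>
    dplyr::summarise(dplyr::across(c("precision", "recall", "f1", "accuracy",
                                     "fpr", "specificity"), mean))
  micro <- class_metrics(sum(tp), sum(fp), sum(fn), sum(tn))[
    , c("precision", "recall", "f1", "accuracy", "fpr", "specificity")]
  # single-label pooling gives FP = FN, so micro precision = recall = F1 =
  # accuracy; short-circuit the harmonic mean to keep the identity exact
  if (micro$precision == micro$recall) micro$f1 <- micro$precision
  structure(list(per_class = per_class, macro = macro, micro = micro,
                 accuracy = safe_div(sum(tp), total), n = total),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: %d items, accuracy %.4f, macro-F1 %.4f>\n",
              x$n, x$accuracy, x$macro$f1))
  invisible(x)
}

# binary ROC/PR points for one score column; positives are score >= threshold
binary_curves <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  P <- sum(y); N <- sum(!y)
  pts <- lapply(thr, function(t) {
    pred <- s >= t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    c(tp = tp, fp = fp)
  })
  tp <- vapply(pts, `[[`, numeric(1), "tp")
  fp <- vapply(pts, `[[`, numeric(1), "fp")
  tpr <- if (P > 0) tp / P else rep(0, length(tp))
  fpr <- if (N > 0) fp / N else rep(0, length(fp))
  precision <- safe_div(tp, tp + fp)
  roc <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1) {
    roc <- dplyr::bind_rows(roc, tibble::tibble(threshold = -Inf, fpr = 1,
                                                tpr = 1))
  }
  pr <- tibble::tibble(threshold = thr, recall = tpr, precision = precision)
  pr <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, recall = 0,
                   precision = if (nrow(pr) > 0) pr$precision[1] else 1), pr)
  auc_roc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                    utils::tail(roc$tpr, -1)) / 2)
  auc_pr <- sum(diff(pr$recall) * (utils::head(pr$precision, -1) +
                                     utils::tail(pr$precision, -1)) / 2)
  list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr, P = P, N = N)
}

#' ROC and PR curves with per-class, micro and macro AUC
#'
#' Sweeps thresholds over the unique scores of each class column
#' (one-vs-rest; `score >= threshold` is positive), building ROC
#' (FPR vs TPR) and PR (recall vs precision) curves with trapezoidal AUC.
#' The micro average pools all (item, class) binary decisions; the macro
#' average is the unweighted mean of per-class AUCs. A class absent from
#' `y_true` has undefined AUC and is excluded from the macro mean (flagged).
#'
#' @param y_true Integer labels in `1..K`, or an `n x K` one-hot matrix.
#' @param scores An `n x K` matrix of finite per-class scores.
#' @return A `classifier_curves` object: list with `roc`, `pr` (tidy
#'   per-class + micro tibbles), and `auc` (per class, `"micro"`,
#'   `"macro"`).
#' @export
roc_pr_curves <- function(y_true, scores) {
  if (!all(is.finite(scores))) tt_abort("scores must be finite")
  K <- ncol(scores)
  if (is.matrix(y_true)) {
    Y <- y_true > 0
  } else {
    Y <- matrix(FALSE, length(y_true), K)
    Y[cbind(seq_along(y_true), y_true)] <- TRUE
  }
  per_class <- lapply(seq_len(K), function(k) binary_curves(Y[, k], scores[, k]))
  roc <- dplyr::bind_rows(lapply(seq_len(K), function(k)
    dplyr::mutate(per_class[[k]]$roc, class = as.character(k),
                  .before = 1)))
  pr <- dplyr::bind_rows(lapply(seq_len(K), function(k)
    dplyr::mutate(per_class[[k]]$pr, class = as.character(k), .before = 1)))
  micro <- binary_curves(as.vector(Y), as.vector(scores))
  roc <- dplyr::bind_rows(roc, dplyr::mutate(micro$roc, class = "micro",
                                             .before = 1))
  pr <- dplyr::bind_rows(pr, dplyr::mutate(micro$pr, class = "micro",
                                           .before = 1))
  defined <- vapply(per_class, function(x) x$P > 0 && x$N > 0, logical(1))
  auc <- tibble::tibble(
    class = c(as.character(seq_len(K)), "micro", "macro"),
    roc_auc = c(ifelse(defined,
                       vapply(per_class, `[[`, numeric(1), "auc_roc"),
                       NA_real_),
                micro$auc_roc,
                mean(vapply(per_class, `[[`, numeric(1), "auc_roc")[defined])),
    pr_auc = c(ifelse(defined,
                      vapply(per_class, `[[`, numeric(1), "auc_pr"),
                      NA_real_),
               micro$auc_pr,
               mean(vapply(per_class, `[[`, numeric(1), "auc_pr")[defined])))
  structure(list(roc = roc, pr = pr, auc = auc,
                 undefined_classes = which(!defined)),
            class = "classifier_curves")
}

#' Critical value of the paired cross-validation t-test
#'
#' Two-sided Student-t critical value at level `alpha` with `df` degrees of
#' freedom; with the default 5 repetitions this is 2.571.
#'
#' @param alpha Significance level (default 0.05).
#' @param df Degrees of freedom (default 5, the repetition count).
#' @return The critical value.
#' @export
cv_ttest_threshold <- function(alpha = 0.05, df = 5) {
  qt(1 - alpha / 2, df)
}

#' Repeated paired cross-validation t-test between two classifiers
#'
#' The repeated two-role paired t-test for comparing learning algorithms on
#' one dataset: in each of `repetitions` rounds the data is split at random
#' into two parts; both classifiers are trained on part 1 and scored on
#' part 2 (difference `p_i1`), then roles are swapped (`p_i2`). With
#' `s_i^2 = (p_i1 - pbar_i)^2 + (p_i2 - pbar_i)^2` the statistic is
#' `t = p_11 / sqrt(mean(s_i^2))` on `df = repetitions` degrees of freedom;
#' the null of equal performance is rejected when `|t|` exceeds the
#' two-sided critical value (2.571 at `alpha = 0.05` with the default 5
#' repetitions).
#'
#' @param data A tibble with (at least) a `label` column, handed to the
#'   builders.
#' @param builder_a,builder_b Functions `(train_data, seed)` returning a
#'   prediction function `(test_data) -> integer labels`.
#' @param repetitions Number of split rounds (default 5).
#' @param train_frac Fraction of the data in the first role's training part
#'   (default 0.5; the complement is used when roles swap).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed driving the splits and the builder seeds.
#' @return A `cv_ttest` object: `t`, `df`, `p_value`, `threshold`,
#'   `reject`, `zero_variance` flag and the per-repetition score pairs.
#' @export
cv_paired_ttest <- function(data, builder_a, builder_b, repetitions = 5,
                            train_frac = 0.5, alpha = 0.05, seed = 1) {
  n <- nrow(data)
  if (n < 4) tt_abort("cv_paired_ttest: dataset too small")
  set.seed(seed)
  accuracy <- function(pred, truth) mean(pred == truth)
  rows <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    idx1 <- sort(sample.int(n, round(n * train_frac)))
    idx2 <- setdiff(seq_len(n), idx1)
    # both builders get the same derived seed, so an algorithm compared
    # against an exact copy of itself trains identically (t = 0)
    seed_r <- (seed + 104729 * r) %% .Machine$integer.max
    diffs <- numeric(2)
    for (role in 1:2) {
      tr <- if (role == 1) idx1 else idx2
      te <- if (role == 1) idx2 else idx1
      pred_a <- builder_a(data[tr, , drop = FALSE], seed_r)
      pred_b <- builder_b(data[tr, , drop = FALSE], seed_r)
      test <- data[te, , drop = FALSE]
      diffs[role] <- accuracy(pred_a(test), test$label) -
        accuracy(pred_b(test), test$label)
    }
    rows[[r]] <- tibble::tibble(repetition = r, p1 = diffs[1], p2 = diffs[2])
  }
  pairs <- dplyr::bind_rows(rows)
  pbar <- (pairs$p1 + pairs$p2) / 2
  s2 <- (pairs$p1 - pbar)^2 + (pairs$p2 - pbar)^2
  zero_variance <- all(s2 == 0)
  t_stat <- if (zero_variance) 0 else pairs$p1[1] / sqrt(mean(s2))
  df <- repetitions
  threshold <- cv_ttest_threshold(alpha, df)
  p_value <- 2 * pt(-abs(t_stat), df)
  structure(list(t = t_stat, df = df, p_value = p_value,
                 threshold = threshold, reject = abs(t_stat) > threshold,
                 zero_variance = zero_variance, pairs = pairs,
                 alpha = alpha, train_frac = train_frac, seed = seed),
            class = "cv_ttest")
}

#' @export
print.cv_ttest <- function(x, ...) {
  cat(sprintf("<cv_ttest: t = %.3f (df = %d), threshold = %.3f, p = %.4f, %s>\n",
              x$t, x$df, x$threshold, x$p_value,
              if (x$reject) "reject H0" else "fail to reject H0"))
  invisible(x)
}
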