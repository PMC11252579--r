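test_that("confusion matrices count true/predicted pairs", {
  M <- confusion_matrix(c(1L, 1L, 2L), c(1L, 2L, 2L), 2)
  expect_equal(unclass(M), matrix(c(1L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  perfect <- confusion_matrix(1:4, 1:4, 4)
  expect_equal(unclass(perfect), diag(1L, 4), ignore_attr = TRUE)
  empty <- confusion_matrix(integer(), integer(), 3)
  expect_equal(sum(empty), 0)
  expect_error(confusion_matrix(c(1L, 5L), c(1L, 1L), 3), "out of range")
})

test_that("metric formulas reproduce hand arithmetic", {
  # single positive class with TP = 3, FP = 1, FN = 2 embedded in 2 classes
  y_true <- c(rep(1L, 5), rep(2L, 4))
  y_pred <- c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L, 2L)
  rep_ <- eval_metrics(confusion_matrix(y_true, y_pred, 2))
  c1 <- rep_$per_class[1, ]
  expect_equal(c1$precision, 0.75)
  expect_equal(c1$recall, 0.6)
  expect_equal(c1$f1, 2 * 0.75 * 0.6 / 1.35)

  diag_rep <- eval_metrics(confusion_matrix(1:3, 1:3, 3))
  expect_true(all(diag_rep$per_class$precision == 1))
  expect_true(all(diag_rep$per_class$recall == 1))
  expect_true(all(diag_rep$per_class$fpr == 0))
  expect_equal(diag_rep$accuracy, 1)
})

test_that("metrics agree with a brute-force oracle on random labelings", {
  set.seed(13)
  for (rep in 1:25) {
    C <- sample(2:6, 1)
    n <- sample(10:60, 1)
    y_true <- sample.int(C, n, replace = TRUE)
    y_pred <- sample.int(C, n, replace = TRUE)
    got <- eval_metrics(confusion_matrix(y_true, y_pred, C))
    for (cls in seq_len(C)) {
      want <- oracle_binary_metrics(y_true, y_pred, cls)
      row <- got$per_class[cls, ]
      expect_equal(row$precision, want$precision)
      expect_equal(row$recall, want$recall)
      expect_equal(row$f1, want$f1)
      expect_equal(row$accuracy, want$accuracy)
      expect_equal(row$fpr, want$fpr)
    }
    # micro-F1 equals accuracy for single-label multiclass, exactly
    expect_identical(got$micro$f1, got$accuracy)
    vals <- unlist(got$per_class[, c("precision", "recall", "f1",
                                     "accuracy", "fpr", "specificity")])
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("metrics(confusion(y, y)) has accuracy 1 for any labeling", {
  set.seed(17)
  for (rep in 1:5) {
    y <- sample.int(4, 30, replace = TRUE)
    expect_equal(eval_metrics(confusion_matrix(y, y, 4))$accuracy, 1)
  }
})

test_that("ROC AUC hits its analytic anchors", {
  # perfectly ranked scores
  y <- c(rep(2L, 5), rep(1L, 5))
  s <- cbind(seq(0.1, 1.0, length.out = 10), seq(1.0, 0.1, length.out = 10))
  curves <- roc_pr_curves(y, s)
  expect_equal(curves$auc$roc_auc[curves$auc$class == "2"], 1)
  # constant scores give chance level
  const <- roc_pr_curves(y, matrix(0.5, 10, 2))
  expect_equal(const$auc$roc_auc[const$auc$class == "1"], 0.5)
  expect_error(roc_pr_curves(y, matrix(c(0.1, NA), 10, 2)), "finite")
})

test_that("binary AUC equals the all-pairs Mann-Whitney probability", {
  set.seed(19)
  n <- 200
  y_true <- sample.int(2, n, replace = TRUE)
  scores <- matrix(round(runif(2 * n), 2), n, 2)  # rounding forces ties
  curves <- roc_pr_curves(y_true, scores)
  for (cls in 1:2) {
    mw <- oracle_auc_mw(y_true == cls, scores[, cls])
    expect_equal(curves$auc$roc_auc[cls], mw, tolerance = 1e-9)
  }
  # macro is the mean of the defined per-class AUCs
  expect_equal(curves$auc$roc_auc[curves$auc$class == "macro"],
               mean(curves$auc$roc_auc[1:2]))
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
  set.seed(23)
  y <- sample.int(3, 80, replace = TRUE)
  s <- matrix(runif(240), 80, 3)
  a1 <- roc_pr_curves(y, s)$auc$roc_auc
  a2 <- roc_pr_curves(y, exp(3 * s))$auc$roc_auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("a class absent from the truth is excluded from the macro average", {
  y <- rep(1:2, each = 10)
  s <- matrix(runif(30 * 1), 20, 3)
  curves <- roc_pr_curves(y, cbind(runif(20), runif(20), runif(20)))
  expect_equal(curves$undefined_classes, 3L)
  expect_true(is.na(curves$auc$roc_auc[3]))
  expect_false(is.na(curves$auc$roc_auc[curves$auc$class == "macro"]))
})

test_that("the paired-cv t-test critical value and null behavior are exact", {
  expect_equal(round(cv_ttest_threshold(0.05, 5), 3), 2.571)

  # deterministic centroid-style builder on a toy feature table
  set.seed(31)
  data <- tibble::tibble(x = c(rnorm(40, -2), rnorm(40, 2)),
                         label = rep(1:2, each = 40))
  centroid_builder <- function(train, seed) {
    mu <- tapply(train$x, train$label, mean)
    function(test) {
      as.integer(names(mu))[max.col(-abs(outer(test$x, mu, "-")),
                                    ties.method = "first")]
    }
  }
  # a classifier compared with an identical copy of itself: t = 0, no reject
  res <- cv_paired_ttest(data, centroid_builder, centroid_builder,
                         repetitions = 5, seed = 3)
  expect_identical(res$t, 0)
  expect_false(res$reject)
  expect_true(res$zero_variance)
  expect_equal(res$df, 5)
  expect_equal(res$threshold, qt(0.975, 5))
})

test_that("a strong classifier is separated from a random guesser", {
  set.seed(37)
  data <- tibble::tibble(x = c(rnorm(60, -2), rnorm(60, 2)),
                         label = rep(1:2, each = 60))
  centroid_builder <- function(train, seed) {
    mu <- tapply(train$x, train$label, mean)
    function(test) {
      as.integer(names(mu))[max.col(-abs(outer(test$x, mu, "-")),
                                    ties.method = "first")]
    }
  }
  random_builder <- function(train, seed) {
    function(test) {
      with_seed_int <- seed
      set.seed(with_seed_int)
      sample(unique(train$label), nrow(test), replace = TRUE)
    }
  }
  rejections <- vapply(1:10, function(r) {
    cv_paired_ttest(data, centroid_builder, random_builder,
                    repetitions = 5, seed = 100 + r)$reject
  }, logical(1))
  expect_gte(mean(rejections), 0.9)
})
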