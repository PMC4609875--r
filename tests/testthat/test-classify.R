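make_blobs <- function(n_per = 15, gap = 6, d = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  list(X = X, y = rep(c(-1L, 1L), each = n_per))
}

test_that("SVM separates distant blobs and predicts the sign of its score", {
  b <- make_blobs()
  m <- train_svm(b$X, b$y, C = 10, sigma = 2)
  pr <- predict(m, b$X)
  expect_equal(mean(pr$pred == b$y), 1)
  expect_identical(pr$pred, ifelse(pr$score > 0, 1L, -1L))
  expect_error(train_svm(b$X, rep(1, 30)), "single class")
})

test_that("duplicating every training point leaves the decision function unchanged", {
  b <- make_blobs(n_per = 10)
  m1 <- train_svm(b$X, b$y, C = 5, sigma = 2)
  m2 <- train_svm(rbind(b$X, b$X), c(b$y, b$y), C = 5, sigma = 2)
  set.seed(3)
  grid <- matrix(runif(40, -2, 8), 20, 2)
  # solver tolerance, not exact arithmetic, bounds the agreement
  expect_equal(predict(m1, grid)$score, predict(m2, grid)$score,
               tolerance = 2e-2)
  expect_identical(predict(m1, grid)$pred, predict(m2, grid)$pred)
})

test_that("leave-one-out evaluation partitions and scores correctly", {
  b <- make_blobs(n_per = 10)
  rep_svm <- loo_evaluate(b$X, b$y, "svm", C = 10, sigma = 2)
  expect_equal(rep_svm$TP + rep_svm$TN + rep_svm$FP + rep_svm$FN, 20)
  expect_equal(rep_svm$accuracy, 1)
  expect_equal(rep_svm$sensitivity, 1)
  expect_equal(rep_svm$specificity, 1)
  expect_equal(rep_svm$auc, 1)
  expect_equal(rep_svm$rmse, 0)

  # null data: accuracy compatible with coin flipping
  set.seed(7)
  Xn <- matrix(rnorm(60 * 5), 60, 5)
  yn <- rep(c(-1L, 1L), 30)
  rep_null <- loo_evaluate(Xn, yn, "svm", C = 1, sigma = 2)
  expect_gt(rep_null$accuracy, 0.2)
  expect_lt(rep_null$accuracy, 0.8)

  gl <- glance(rep_svm)
  expect_equal(gl$accuracy, 1)
  expect_equal(nrow(tidy(rep_svm)), 20)
})

test_that("confusion metrics use tumor-positive coding and NA on empty denominators", {
  cm <- confusion_metrics(c(1, 1, 1, -1), c(1, 1, 1, 1))
  expect_equal(cm$sensitivity, 0.75)
  expect_true(is.na(cm$specificity))
  all_right <- confusion_metrics(c(1, -1), c(1, -1))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
})

test_that("error scores work on the 0/1 encoding and obey rmse >= mae", {
  es <- error_scores(c(1, 1, 1, -1), c(1, 1, 1, 1))
  expect_equal(es$mae, 0.25)
  expect_equal(es$rmse, 0.5)
  expect_equal(error_scores(c(1, -1), c(1, -1)),
               list(rmse = 0, mae = 0))
  for (s in 1:10) {
    set.seed(s)
    p <- sample(c(-1, 1), 20, replace = TRUE)
    o <- sample(c(-1, 1), 20, replace = TRUE)
    e <- error_scores(p, o)
    expect_gte(e$rmse, e$mae)
  }
})

test_that("ROC area matches the pair-counting oracle and handles edge cases", {
  expect_equal(roc_curve(c(3, 2, 1, 0), c(1, 1, -1, -1))$auc, 1)
  for (s in 1:40) {
    set.seed(s)
    n <- sample(6:20, 1)
    labels <- c(rep(1, 3), sample(c(-1, 1), n - 3, replace = TRUE))
    labels[1:2] <- -1  # guarantee both classes
    scores <- round(rnorm(n), 1)  # ties occur
    expect_equal(roc_curve(scores, labels)$auc, brute_auc(scores, labels))
  }
  # permuted labels average to chance
  set.seed(1)
  aucs <- replicate(200, {
    roc_curve(rnorm(20), sample(rep(c(-1, 1), 10)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  r <- roc_curve(c(3, 2, 1), c(1, -1, -1))
  expect_named(r$operating_point, c("fp", "tp"))
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC area agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(30)
  labels <- sample(rep(c(-1, 1), 15))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(roc_curve(scores, labels)$auc, ref)
})

test_that("classifier comparison degenerates to p = 1 and detects real gaps", {
  same <- rep(c(0, 1), 10)
  expect_equal(compare_classifiers(same, same)$p_value, 1)
  set.seed(3)
  worse <- pmin(same + rbinom(20, 1, 0.8), 1)
  res <- compare_classifiers(worse, same)
  expect_lt(res$p_value, 0.05)
  # shifting both members of each pair leaves the statistic unchanged
  res2 <- compare_classifiers(worse + 5, same + 5)
  expect_equal(res$statistic, res2$statistic)
})

test_that("kNN baseline classifies separable blobs and has no ties for odd k", {
  b <- make_blobs(n_per = 12, gap = 6)
  rep_knn <- knn_baseline(b$X, b$y, k = 5)
  expect_gte(rep_knn$accuracy, 0.95)
  expect_true(all(rep_knn$predictions$pred %in% c(-1L, 1L)))
  expect_error(loo_evaluate(b$X, b$y, "knn", k = 4), "odd")
})

test_that("hyperparameter grid tuning prefers accurate, moderate settings", {
  b <- make_blobs(n_per = 10, gap = 6)
  tuned <- tune_svm(b$X, b$y, folds = 5, seed = 1)
  expect_equal(tuned$cv_accuracy, 1)
  expect_equal(nrow(tuned$grid), 16)
  rep_tuned <- loo_evaluate(b$X, b$y, "svm", C = tuned$C, sigma = tuned$sigma)
  expect_equal(rep_tuned$accuracy, 1)
})
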