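sepToy <- function(n = 8) {
  # linearly separable 2-D toy set, margin >= 1
  X <- rbind(cbind(rnorm(n / 2, -2, 0.2), rnorm(n / 2, -2, 0.2)),
             cbind(rnorm(n / 2, 2, 0.2), rnorm(n / 2, 2, 0.2)))
  colnames(X) <- c("u", "v")
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

test_that("the linear SVM separates a separable toy set", {
  set.seed(41)
  toy <- sepToy(16)
  clf <- trainClassifier(toy$X, toy$y)
  pred <- predictLabels(clf, toy$X)
  expect_equal(pred$label, toy$y)
  expect_error(trainClassifier(toy$X, rep(1, 16)), "single class")
})

test_that("thresholding is strict: probability at the threshold is negative", {
  set.seed(42)
  toy <- sepToy(16)
  clf <- trainClassifier(toy$X, toy$y)
  p <- predictLabels(clf, toy$X)$probability
  expect_identical(as.integer(p > 0.5), predictLabels(clf, toy$X)$label)
  # degenerate thresholds via the strict rule, checked directly
  expect_identical(as.integer(0.5 > 0.5), 0L)
  expect_identical(predictLabels(clf, toy$X, threshold = 1 - 1e-12)$label,
                   as.integer(p > 1 - 1e-12))
})

test_that("confusion counts tabulate the 2x2 outcomes", {
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  expect_equal(confusionCounts(c(1, 1, 0, 0), c(0, 0, 1, 1)),
               c(TP = 0L, FP = 2L, TN = 0L, FN = 2L))
  expect_equal(confusionCounts(c(1, 0, 1, 0, 0), c(1, 1, 0, 0, 0)),
               c(TP = 1L, FP = 1L, TN = 2L, FN = 1L))
  expect_error(confusionCounts(c(1, 2), c(0, 1)), "binary")
})

test_that("metrics implement their defining formulas", {
  m <- computeMetrics(c(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(unname(m), rep(0.5, 5))
  m2 <- computeMetrics(c(TP = 30, FP = 10, TN = 50, FN = 10))
  expect_equal(m2[["precision"]], 30 / 40)
  expect_equal(m2[["sensitivity"]], 30 / 40)
  expect_equal(m2[["specificity"]], 50 / 60)
  expect_equal(m2[["accuracy"]], 80 / 100)
  expect_equal(m2[["f1"]], 2 * 0.75 * 0.75 / 1.5)
  expect_warning(m3 <- computeMetrics(c(TP = 0, FP = 0, TN = 5, FN = 5)),
                 "precision")
  expect_equal(m3[["precision"]], 0)
  expect_error(computeMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "no")
})

test_that("published baseline f1 values satisfy the f1 identity", {
  f1 <- function(p, r) 2 * p * r / (p + r)
  for (meth in c("Logistic Regression", "Naive Bayes", "KNN",
                 "Random Forest")) {
    row <- refBase[refBase$method == meth, ]
    expect_equal(round(f1(row$precision, row$sensitivity), 2), row$f1)
  }
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  set.seed(43)
  for (rep in 1:6) {
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + 0.8 * y
    if (rep %% 2 == 0) s <- round(s, 1)  # force ties
    got <- rocAuc(s, y)$auc
    rk <- rank(s)  # midranks handle ties like the trapezoid does
    u <- sum(rk[y == 1]) - sum(y) * (sum(y) + 1) / 2
    expect_equal(got, u / (sum(y) * sum(1 - y)), tolerance = 1e-9)
  }
})

test_that("ROC endpoints and degenerate scores behave", {
  y <- c(1, 1, 0, 0)
  perfect <- rocAuc(c(0.9, 0.8, 0.2, 0.1), y)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(perfect$points$tpr[nrow(perfect$points)], 1)
  expect_true(all(diff(perfect$points$fpr) >= 0))
  expect_true(all(diff(perfect$points$tpr) >= 0))
  expect_equal(rocAuc(rep(0.5, 4), y)$auc, 0.5)  # all tied -> chance
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("null scores give AUC near 0.5", {
  set.seed(44)
  y <- rbinom(2000, 1, 0.5)
  s <- rnorm(2000)
  auc <- rocAuc(s, y)$auc
  n1 <- sum(y); n0 <- sum(1 - y)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("stratified folds partition the data and are reproducible", {
  set.seed(45)
  X <- matrix(rnorm(400), ncol = 2)
  y <- rep(c(0, 1), each = 100)
  X[y == 1, ] <- X[y == 1, ] + 1.5
  cv1 <- kfoldCV(X, y, k = 5, seed = 9)
  cv2 <- kfoldCV(X, y, k = 5, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$cvMean, cv2$cvMean)
  expect_setequal(unique(cv1$folds), 1:5)
  # stratification: class balance per fold within rounding
  for (f in 1:5)
    expect_equal(sum(y[cv1$folds == f]), 20)
  # a majority-class dummy scores the majority prior exactly
  dummy <- function(Xt, yt, s) {
    maj <- as.integer(mean(yt) > 0.5)
    structure(list(maj = maj),
              predictFun = function(fit, Z) rep(fit$maj, nrow(Z)))
  }
  yImb <- rep(c(0, 1), c(140, 60))
  cvd <- kfoldCV(X, yImb, k = 5, seed = 2, trainFun = dummy)
  expect_equal(cvd$cvMean, 0.7)
})

test_that("the baseline harness is deterministic and internally consistent", {
  set.seed(46)
  n <- 160
  X <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(X[, 1] + X[, 2] + rnorm(n, sd = 0.4) > 0)
  fm <- new("FeatureMatrix", values = X, label = as.numeric(y),
            normParams = data.frame(feature = c("a", "b"), min = 0, max = 1),
            trainIds = character())
  tab1 <- runBaselines(fm, methods = c("lr", "nb", "knn"), cvFolds = 4,
                       seed = 7)
  tab2 <- runBaselines(fm, methods = c("lr", "nb", "knn"), cvFolds = 4,
                       seed = 7)
  expect_equal(tab1, tab2)
  expect_true(all(tab1$status == "ok"))
  ok <- tab1$precision + tab1$sensitivity > 0
  expect_equal(tab1$f1[ok],
               2 * tab1$precision[ok] * tab1$sensitivity[ok] /
                 (tab1$precision[ok] + tab1$sensitivity[ok]),
               tolerance = 1e-12)
  # strong planted signal: every learner does well
  expect_true(all(tab1$auc > 0.8))
})
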