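#' Train the linear-kernel SVM myopia classifier
#'
#' Soft-margin SVM with linear kernel and penalty `C` (default 1.0), fitted
#' with Platt-type sigmoid calibration so that class-1 (myopic)
#' probabilities can be thresholded. Deterministic given `seed` (the
#' internal calibration cross-validation is seeded).
#'
#' @param features a [FeatureMatrix-class], or a numeric matrix with
#'   `labels` supplied.
#' @param labels binary vector (ignored when `features` is a
#'   [FeatureMatrix-class]).
#' @param C penalty coefficient (> 0).
#' @param seed integer seed.
#' @return a classifier handle (list with the fitted `e1071::svm` object and
#'   the feature schema).
#' @export
trainClassifier <- function(features, labels = NULL, C = 1.0, seed = 1) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  y <- if (is(features, "FeatureMatrix")) featureLabels(features)
       else as.numeric(labels)
  if (anyNA(X) || anyNA(y)) stop("missing values in features or labels")
  if (length(unique(y)) < 2)
    stop("training data contain a single class")
  stopifnot(C > 0)
  set.seed(seed)
  fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                    cost = C, probability = TRUE, scale = FALSE)
  structure(list(fit = fit, featureNames = colnames(X), C = C),
            class = "myopiaClassifier")
}

#' @export
print.myopiaClassifier <- function(x, ...) {
  cat(sprintf("Linear-SVM myopia classifier (C = %g, %d features)\n",
              x$C, length(x$featureNames)))
  invisible(x)
}

#' Probability-thresholded predictions
#'
#' Returns the calibrated class-1 probability per student and the hard
#' label, 1 iff probability strictly exceeds the threshold (a probability
#' exactly at the threshold yields the negative class).
#'
#' @param clf classifier from [trainClassifier()].
#' @param features matrix or [FeatureMatrix-class] matching the training
#'   schema.
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return list with `probability` and `label`.
#' @export
predictLabels <- function(clf, features, threshold = 0.5) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  if (!is.null(colnames(X)) && !is.null(clf$featureNames)) {
    if (!all(clf$featureNames %in% colnames(X)))
      stop("features do not match the training schema")
    X <- X[, clf$featureNames, drop = FALSE]
  } else if (!is.null(clf$featureNames) &&
             ncol(X) != length(clf$featureNames)) {
    stop("features do not match the training schema")
  }
  pr <- predict(clf$fit, X, probability = TRUE)
  prob <- attr(pr, "probabilities")[, "1"]
  list(probability = unname(prob),
       label = as.integer(prob > threshold))
}

#' Confusion counts for binary predictions
#'
#' Positive class = myopic (1).
#'
#' @param truth,predicted binary 0/1 vectors of equal length.
#' @return named integer vector TP, FP, TN, FN.
#' @export
confusionCounts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be binary 0/1")
  c(TP = sum(truth == 1 & predicted == 1),
    FP = sum(truth == 0 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FN = sum(truth == 1 & predicted == 0))
}

#' Metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), sensitivity (recall,
#' TPR) = TP/(TP+FN), specificity = TN/(TN+FP), f1 = 2PR/(P+R). A metric
#' with zero denominator is reported as 0 with a warning note rather than
#' failing.
#'
#' @param counts named vector from [confusionCounts()].
#' @return named numeric vector with attribute `notes` (character).
#' @export
computeMetrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (sum(counts) == 0) stop("no evaluated samples")
  notes <- character()
  safe <- function(num, den, name) {
    if (den == 0) {
      notes <<- c(notes, sprintf("%s undefined (zero denominator)", name))
      return(0)
    }
    num / den
  }
  p <- safe(counts["TP"], counts["TP"] + counts["FP"], "precision")
  s <- safe(counts["TP"], counts["TP"] + counts["FN"], "sensitivity")
  out <- c(accuracy = unname((counts["TP"] + counts["TN"]) / sum(counts)),
           precision = unname(p),
           sensitivity = unname(s),
           specificity = unname(safe(counts["TN"],
                                     counts["TN"] + counts["FP"],
                                     "specificity")),
           f1 = unname(safe(2 * p * s, p + s, "f1")))
  if (length(notes)) {
    warning(paste(notes, collapse = "; "))
    attr(out, "notes") <- notes
  }
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores, tied scores stepping
#' simultaneously; the polyline runs from (0,0) to (1,1) and the AUC is the
#' trapezoidal area (equal to the normalized Mann-Whitney U statistic).
#'
#' @param probabilities numeric scores, larger = more positive.
#' @param truth binary 0/1 vector; both classes must be present.
#' @return list with `points` (data.frame fpr, tpr) and `auc`.
#' @export
rocAuc <- function(probabilities, truth) {
  stopifnot(length(probabilities) == length(truth))
  nPos <- sum(truth == 1); nNeg <- sum(truth == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  ord <- order(probabilities, decreasing = TRUE)
  s <- probabilities[ord]; t <- truth[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(t == 1)[keep] / nPos)
  fpr <- c(0, cumsum(t == 0)[keep] / nNeg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin. Returns integer fold id per observation.
.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class with a seeded shuffle, disjoint and
#' covering. If a fold's training part lacks a class the data are refolded
#' with a warning (a different derived seed).
#'
#' @param features [FeatureMatrix-class] or matrix (+ `labels`).
#' @param labels binary vector when `features` is a matrix.
#' @param k number of folds (>= 2), default 10.
#' @param C SVM penalty.
#' @param threshold decision threshold.
#' @param seed integer seed.
#' @param trainFun optional custom `function(X, y, seed)` returning an
#'   object with a `function(model, X)` predictor in `attr(,"predictFun")`;
#'   default trains the linear SVM.
#' @return list with `foldAccuracy`, `cvMean`, `folds`.
#' @export
kfoldCV <- function(features, labels = NULL, k = 10, C = 1.0,
                    threshold = 0.5, seed = 1, trainFun = NULL) {
  X <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  y <- if (is(features, "FeatureMatrix")) featureLabels(features)
       else as.numeric(labels)
  stopifnot(k >= 2, nrow(X) >= k)
  fold <- .stratifiedFolds(y, k, seed)
  for (attempt in 1:10) {
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))
    if (ok) break
    warning("a fold's training part lacked a class; refolding")
    fold <- .stratifiedFolds(y, k, seed + attempt)
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (is.null(trainFun)) {
      clf <- trainClassifier(X[tr, , drop = FALSE], y[tr], C = C,
                             seed = seed + f)
      pred <- predictLabels(clf, X[!tr, , drop = FALSE], threshold)$label
    } else {
      clf <- trainFun(X[tr, , drop = FALSE], y[tr], seed + f)
      pred <- attr(clf, "predictFun")(clf, X[!tr, , drop = FALSE])
    }
    mean(pred == y[!tr])
  }, numeric(1))
  list(foldAccuracy = acc, cvMean = mean(acc), folds = fold)
}

#' Full evaluation of a classifier on a holdout
#'
#' @param truth binary truth on the holdout.
#' @param probability class-1 probabilities on the holdout.
#' @param threshold decision threshold.
#' @param cv optional result of [kfoldCV()] to attach.
#' @return an [EvalReport-class].
#' @export
evalReport <- function(truth, probability, threshold = 0.5, cv = NULL) {
  pred <- as.integer(probability > threshold)
  counts <- confusionCounts(truth, pred)
  notes <- character()
  metrics <- withCallingHandlers(
    computeMetrics(counts),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  roc <- rocAuc(probability, truth)
  new("EvalReport", counts = counts, metrics = metrics, auc = roc$auc,
      rocPoints = roc$points,
      cvFolds = if (is.null(cv)) numeric() else cv$foldAccuracy,
      cvMean = if (is.null(cv)) numeric() else cv$cvMean,
      notes = notes)
}

# Baseline learners: each returns list(prob = function(X) class-1
# probabilities) after fitting on (X, y).
.baselineFits <- function(name, X, y, seed) {
  set.seed(seed)
  switch(name,
    svm = {
      clf <- trainClassifier(X, y, seed = seed)
      list(prob = function(Z) predictLabels(clf, Z)$probability)
    },
    lr = {
      df <- data.frame(y = y, X)
      fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      list(prob = function(Z)
        unname(predict(fit, data.frame(Z), type = "response")))
    },
    nb = {
      fit <- e1071::naiveBayes(X, factor(y, levels = c(0, 1)))
      list(prob = function(Z) unname(predict(fit, Z, type = "raw")[, "1"]))
    },
    knn = {
      list(prob = function(Z) {
        pr <- class::knn(X, Z, factor(y, levels = c(0, 1)), k = 5,
                         prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      })
    },
    rf = {
      fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)))
      list(prob = function(Z) unname(predict(fit, Z, type = "prob")[, "1"]))
    },
    bpnn = {
      fit <- nnet::nnet(X, y, size = 16, decay = 1e-3, maxit = 200,
                        trace = FALSE)
      list(prob = function(Z) drop(predict(fit, Z)))
    },
    stop(sprintf("unknown baseline '%s'", name)))
}

#' Baseline comparison harness
#'
#' Trains the linear SVM and the requested baselines (logistic regression
#' `lr`, naive Bayes `nb`, k-nearest neighbours `knn`, random forest `rf`,
#' single-hidden-layer backprop network `bpnn`, 16 hidden units) under one
#' identical stratified 80/20 holdout and metric harness, plus a 10-fold CV
#' accuracy each. Library-default hyper-parameters are used and recorded.
#' A failing learner is marked failed; the others are unaffected.
#'
#' @param features a [FeatureMatrix-class].
#' @param methods baselines to run (always includes `svm` first).
#' @param threshold decision threshold.
#' @param cvFolds folds for the CV column.
#' @param seed integer seed (split, folds and learners all derive from it).
#' @return data.frame: method, accuracy, cv, precision, sensitivity, f1,
#'   auc, specificity, status.
#' @export
runBaselines <- function(features,
                         methods = c("lr", "nb", "knn", "rf", "bpnn"),
                         threshold = 0.5, cvFolds = 10, seed = 1) {
  X <- featureValues(features)
  y <- featureLabels(features)
  methods <- unique(c("svm", methods))
  fold <- .stratifiedFolds(y, 5, deriveSeed(seed, "holdout"))
  test <- fold == 1  # stratified 80/20 holdout
  rows <- lapply(methods, function(mname) {
    res <- tryCatch({
      fit <- .baselineFits(mname, X[!test, , drop = FALSE], y[!test],
                           deriveSeed(seed, mname))
      prob <- fit$prob(X[test, , drop = FALSE])
      m <- suppressWarnings(
        computeMetrics(confusionCounts(y[test],
                                       as.integer(prob > threshold))))
      auc <- rocAuc(prob, y[test])$auc
      cvm <- kfoldCV(X, y, k = cvFolds, seed = deriveSeed(seed, "cv"),
                     trainFun = function(Xt, yt, s) {
                       f <- .baselineFits(mname, Xt, yt, s)
                       attr(f, "predictFun") <-
                         function(fit, Z)
                           as.integer(fit$prob(Z) > threshold)
                       f
                     })$cvMean
      data.frame(method = mname, accuracy = m["accuracy"], cv = cvm,
                 precision = m["precision"], sensitivity = m["sensitivity"],
                 f1 = m["f1"], auc = auc, specificity = m["specificity"],
                 status = "ok", row.names = NULL)
    }, error = function(e)
      data.frame(method = mname, accuracy = NA_real_, cv = NA_real_,
                 precision = NA_real_, sensitivity = NA_real_,
                 f1 = NA_real_, auc = NA_real_, specificity = NA_real_,
                 status = paste("failed:", conditionMessage(e)),
                 row.names = NULL))
    res
  })
  do.call(rbind, rows)
}
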