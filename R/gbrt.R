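#' Fit a gradient-boosted regression tree ensemble (squared loss)
#'
#' From-scratch stage-wise boosting. The initial learner is the constant
#' minimizing the squared loss, \eqn{f_0 = \bar y}. At each round m the
#' pseudo-residuals under squared loss are \eqn{r_{im} = y_i - f_{m-1}(x_i)};
#' a depth-bounded CART regression tree is grown on them by greedy
#' variance-reduction splits, each leaf takes the mean residual of its
#' region, and the fit is updated as
#' \eqn{f_m = f_{m-1} + \nu \sum_j c_{mj} I(x \in R_{mj})} with shrinkage
#' \eqn{\nu}. Training MSE is non-increasing in m for \eqn{\nu \le 1}.
#'
#' @param features numeric matrix or data.frame (no missing cells).
#' @param target numeric response vector.
#' @param rounds number of boosting rounds M (>= 1).
#' @param shrinkage learning rate in (0, 1].
#' @param maxDepth maximum tree depth (1 = stumps).
#' @param minLeaf minimum observations per leaf.
#' @return a [GbrtModel-class].
#' @examples
#' m <- gbrtFit(matrix(0:3, ncol = 1), c(0, 0, 10, 10),
#'              rounds = 1, shrinkage = 1, maxDepth = 1, minLeaf = 1)
#' gbrtPredict(m, matrix(0:3, ncol = 1))  # 0 0 10 10
#' @export
gbrtFit <- function(features, target, rounds = 100, shrinkage = 0.1,
                    maxDepth = 3, minLeaf = 5) {
  X <- as.matrix(features)
  if (!is.numeric(X) || anyNA(X)) stop("features must be numeric, no NA")
  y <- as.numeric(target)
  if (anyNA(y)) stop("target must not contain missing values")
  if (nrow(X) != length(y)) stop("features/target length mismatch")
  stopifnot(rounds >= 1, shrinkage > 0, shrinkage <= 1, minLeaf >= 1)
  if (nrow(X) < 2 * minLeaf)
    stop("need at least 2 * minLeaf observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  n <- nrow(X)
  # feature orderings are fixed across rounds: sort once
  ord <- lapply(seq_len(ncol(X)), function(j) order(X[, j]))
  f <- rep(mean(y), n)
  f0 <- f[1]
  trees <- vector("list", rounds)
  for (m in seq_len(rounds)) {
    r <- y - f
    tr <- .growTree(X, r, ord, rep(TRUE, n), depth = 0,
                    maxDepth = maxDepth, minLeaf = minLeaf)
    trees[[m]] <- tr$node
    f <- f + shrinkage * tr$pred
  }
  new("GbrtModel", f0 = f0, shrinkage = shrinkage, trees = trees,
      featureNames = colnames(X), rounds = as.integer(rounds))
}

# Grow one CART regression tree on residuals r restricted to `mask`.
# Returns list(node, pred) where pred is the full-length fitted vector
# (zero outside the mask).
.growTree <- function(X, r, ord, mask, depth, maxDepth, minLeaf) {
  n <- sum(mask)
  leaf <- function() {
    v <- mean(r[mask])
    list(node = list(leaf = TRUE, value = v),
         pred = ifelse(mask, v, 0))
  }
  if (depth >= maxDepth || n < 2 * minLeaf) return(leaf())
  sp <- .bestSplit(X, r, ord, mask, minLeaf)
  if (is.null(sp)) return(leaf())
  lmask <- mask & (X[, sp$var] <= sp$val)
  rmask <- mask & !(X[, sp$var] <= sp$val)
  L <- .growTree(X, r, ord, lmask, depth + 1, maxDepth, minLeaf)
  R <- .growTree(X, r, ord, rmask, depth + 1, maxDepth, minLeaf)
  list(node = list(leaf = FALSE, var = sp$var, val = sp$val,
                   left = L$node, right = R$node),
       pred = L$pred + R$pred)
}

# Exhaustive greedy split search: for each feature, scan the node's points
# in presorted order and maximize the two-child sum-of-squares explained,
# sum_L^2/n_L + sum_R^2/n_R. Ties go to the first feature / leftmost cut.
.bestSplit <- function(X, r, ord, mask, minLeaf) {
  best <- NULL
  bestGain <- -Inf
  for (j in seq_len(ncol(X))) {
    idx <- ord[[j]][mask[ord[[j]]]]
    xs <- X[idx, j]
    n <- length(xs)
    if (n < 2 * minLeaf) next
    cums <- cumsum(r[idx])
    tot <- cums[n]
    i <- seq_len(n - 1)
    cumL <- cums[i]
    valid <- i >= minLeaf & (n - i) >= minLeaf & xs[i] < xs[i + 1]
    if (!any(valid)) next
    gain <- rep(-Inf, n - 1)
    gain[valid] <- cumL[valid]^2 / i[valid] +
      (tot - cumL[valid])^2 / (n - i[valid])
    k <- which.max(gain)
    if (gain[k] > bestGain + 1e-12) {
      bestGain <- gain[k]
      best <- list(var = j, val = (xs[k] + xs[k + 1]) / 2)
    }
  }
  best
}

#' Predict from a boosted ensemble
#'
#' \eqn{f_M(x) = f_0 + \nu \sum_m \sum_j c_{mj} I(x \in R_{mj})};
#' deterministic, row-wise.
#'
#' @param model a [GbrtModel-class].
#' @param features matrix/data.frame whose columns cover the training
#'   schema (matched by name when named).
#' @return numeric vector of predictions.
#' @export
gbrtPredict <- function(model, features) {
  X <- as.matrix(features)
  if (!is.null(colnames(X))) {
    if (!all(model@featureNames %in% colnames(X)))
      stop(sprintf("features missing column(s): %s",
                   paste(setdiff(model@featureNames, colnames(X)),
                         collapse = ", ")))
    X <- X[, model@featureNames, drop = FALSE]
  } else if (ncol(X) != length(model@featureNames)) {
    stop("feature count does not match the training schema")
  }
  pred <- rep(model@f0, nrow(X))
  for (tr in model@trees)
    pred <- pred + model@shrinkage * .predictTree(tr, X)
  pred
}

.predictTree <- function(node, X) {
  out <- numeric(nrow(X))
  rec <- function(nd, idx) {
    if (!length(idx)) return()
    if (nd$leaf) { out[idx] <<- nd$value; return() }
    go <- X[idx, nd$var] <= nd$val
    rec(nd$left, idx[go])
    rec(nd$right, idx[!go])
  }
  rec(node, seq_len(nrow(X)))
  out
}

#' @describeIn gbrtPredict `predict` method for [GbrtModel-class].
#' @param object a [GbrtModel-class].
#' @param newdata feature matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "GbrtModel",
          function(object, newdata, ...) gbrtPredict(object, newdata))
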