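#' Fitting goodness: ratio of prediction spread to data spread
#'
#' \deqn{R^2 = \sum_i (f(x_i) - \bar x)^2 / \sum_i (x_i - \bar x)^2}
#' with \eqn{\bar x} the mean of the actual values. This is *not* the usual
#' \eqn{1 - SSE/SST}: identical predictions give 1, a constant prediction at
#' the data mean gives 0, and over-dispersed predictions can exceed 1 (a
#' warning is emitted when that happens).
#'
#' @param actual numeric vector (non-constant, length >= 2).
#' @param predicted numeric vector of the same length.
#' @return nonnegative scalar.
#' @export
fittingGoodness <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  if (length(actual) < 2) stop("need at least 2 observations")
  xbar <- mean(actual)
  denom <- sum((actual - xbar)^2)
  if (denom == 0) stop("actual values are constant (zero spread)")
  r2 <- sum((predicted - xbar)^2) / denom
  if (r2 > 1)
    warning(sprintf("fitting goodness %.3f exceeds 1 (over-dispersed %s",
                    r2, "predictions)"))
  r2
}

#' Absolute error rate at a tolerance
#'
#' Fraction of predictions whose absolute error is *not* strictly within the
#' tolerance: \eqn{r = 1 - n/m}, where m is the total count and n the number
#' of cases with \eqn{|actual - predicted| < y} (strict).
#'
#' @param actual,predicted numeric vectors of equal, positive length.
#' @param tolerance the error range y (> 0), in target units.
#' @return proportion in [0, 1].
#' @export
absoluteErrorRate <- function(actual, predicted, tolerance = 0.5) {
  stopifnot(length(actual) == length(predicted))
  if (!length(actual)) stop("empty input")
  if (tolerance <= 0) stop("tolerance must be positive")
  1 - mean(abs(actual - predicted) < tolerance)
}

#' The REP model-selection statistic
#'
#' \eqn{REP = R^2 / r}: fitting goodness divided by absolute error rate.
#' Larger is better; a zero error rate (every prediction within tolerance)
#' yields `Inf`, the best possible score.
#'
#' @param rSquared nonnegative fitting goodness (see [fittingGoodness()]).
#' @param errorRate absolute error rate in [0, 1].
#' @param tolerance the tolerance the error rate was computed at (recorded).
#' @return a [RepScore-class].
#' @examples
#' repScore(0.789, 0.145)  # REP = 5.441
#' @export
repScore <- function(rSquared, errorRate, tolerance = 0.5) {
  if (rSquared < 0) stop("rSquared must be nonnegative")
  if (errorRate < 0 || errorRate > 1) stop("errorRate must be in [0, 1]")
  rep <- if (errorRate == 0) Inf else rSquared / errorRate
  new("RepScore", rSquared = rSquared, errorRate = errorRate,
      tolerance = tolerance, rep = rep)
}

#' Pick the REP-optimal train proportion from a sweep table
#'
#' Computes `REP = R2 / r` row-wise and returns the proportion of the
#' maximizing row; ties (including multiple zero error rates) are broken
#' toward the larger proportion, i.e. more training data.
#'
#' @param sweep data.frame with columns `p`, `R2`, `r` (a `REP` column, if
#'   absent, is added).
#' @return list with `p` (chosen proportion) and `sweep` (table with REP).
#' @export
selectRepOptimal <- function(sweep) {
  stopifnot(all(c("p", "R2", "r") %in% names(sweep)))
  sweep$REP <- ifelse(sweep$r == 0, Inf, sweep$R2 / sweep$r)
  best <- which(sweep$REP == max(sweep$REP))
  best <- best[which.max(sweep$p[best])]
  list(p = sweep$p[best], sweep = sweep)
}

# Assemble the RA imputation design: one row per (student, grade >= 2).
# Features: the grade, grade-1 RA, the student's observed RA at the *other*
# grades distilled into a per-student line (extrapolated value at the target
# grade, its slope, and the number of supporting observations -- the target
# cell itself is always excluded, so training rows never see their own
# value), and the student's reduced non-RA factors.
.imputationDesign <- function(cohort, factors) {
  factors <- setdiff(factors, "RA")
  gl <- gradeLevels(cohort)
  ra <- assay(cohort, "RA")
  red <- studentFeatures(cohort, factors, availableCase = TRUE)
  ok <- complete.cases(red) & !is.na(ra[, 1])
  rows <- expand.grid(si = which(ok), gi = 2:length(gl))

  # per-student sufficient statistics of the observed RA cells
  obs <- !is.na(ra)
  gmat <- matrix(gl, nrow(ra), ncol(ra), byrow = TRUE)
  Sn <- rowSums(obs)
  Sg <- rowSums(gmat * obs)
  Sv <- rowSums(ifelse(obs, ra, 0))
  Sgv <- rowSums(ifelse(obs, gmat * ra, 0))
  Sgg <- rowSums(gmat^2 * obs)

  si <- rows$si; gi <- rows$gi; gstar <- gl[gi]
  inObs <- obs[cbind(si, gi)]
  v <- ifelse(inObs, ra[cbind(si, gi)], 0)
  n <- Sn[si] - inObs
  sg <- Sg[si] - inObs * gstar
  sv <- Sv[si] - v
  sgv <- Sgv[si] - v * gstar
  sgg <- Sgg[si] - inObs * gstar^2
  den <- n * sgg - sg^2
  slope <- ifelse(n >= 2 & den > 0, (n * sgv - sg * sv) / den, 0)
  slope[!is.finite(slope)] <- 0
  extrap <- ifelse(n > 0, sv / n + slope * (gstar - sg / n), ra[si, 1])

  X <- cbind(grade = gstar, RA1 = ra[si, 1], raExtrap = extrap,
             raSlope = slope, raObsN = n, red[si, , drop = FALSE])
  rownames(X) <- NULL
  list(X = as.matrix(X), y = ra[cbind(si, gi)],
       student = studentIds(cohort)[si], grade = gstar,
       skipped = studentIds(cohort)[!ok])
}

#' Select the RA imputation model by sweeping the train proportion
#'
#' Implements the REP-driven model-selection flow: the complete records D
#' (student-grade rows with observed RA) are split by student into training
#' and test sets at each proportion of `pGrid`; a GBRT is fitted on the
#' training rows and scored on the test rows with [fittingGoodness()] and
#' [absoluteErrorRate()]; the proportion maximizing REP wins and its model
#' (refitted deterministically on the same split) is returned.
#'
#' @param cohort a [MyopiaCohort-class] (RA may be partially missing; rows
#'   with observed RA form D).
#' @param factors predictor factors (a [FeatureSubset-class] or character);
#'   RA itself is excluded from the reductions -- the always-observed
#'   grade-1 RA and the grade number are used instead.
#' @param pGrid train proportions to sweep, default `seq(0.1, 0.9, 0.1)`.
#' @param tolerance error range y for the error rate, diopters.
#' @param rounds,shrinkage,maxDepth,minLeaf GBRT hyper-parameters.
#' @param seed split seed.
#' @param minTrain,minTest minimum usable split sizes; proportions breaking
#'   them are skipped with a warning.
#' @return list with `model` ([GbrtModel-class]), `p` (chosen proportion),
#'   `sweep` (data.frame p, R2, r, REP), `tolerance`, `design`.
#' @export
selectImputationModel <- function(cohort, factors, pGrid = seq(0.1, 0.9, 0.1),
                                  tolerance = 0.5, rounds = 100,
                                  shrinkage = 0.1, maxDepth = 3, minLeaf = 5,
                                  seed = 1, minTrain = 2 * minLeaf,
                                  minTest = 5) {
  stopifnot(all(pGrid > 0 & pGrid < 1))
  if (is(factors, "FeatureSubset")) factors <- subsetFactors(factors)
  des <- .imputationDesign(cohort, factors)
  obs <- !is.na(des$y)
  X <- des$X[obs, , drop = FALSE]
  y <- des$y[obs]
  stu <- des$student[obs]
  uStu <- unique(stu)
  set.seed(seed)
  shuffled <- sample(uStu)
  fitAt <- function(p) {
    nTrain <- round(p * length(uStu))
    trainStu <- shuffled[seq_len(nTrain)]
    tr <- stu %in% trainStu
    if (sum(tr) < minTrain || sum(!tr) < minTest) return(NULL)
    model <- gbrtFit(X[tr, , drop = FALSE], y[tr], rounds = rounds,
                     shrinkage = shrinkage, maxDepth = maxDepth,
                     minLeaf = minLeaf)
    pred <- gbrtPredict(model, X[!tr, , drop = FALSE])
    list(model = model,
         R2 = suppressWarnings(fittingGoodness(y[!tr], pred)),
         r = absoluteErrorRate(y[!tr], pred, tolerance))
  }
  rows <- lapply(pGrid, function(p) {
    res <- fitAt(p)
    if (is.null(res)) {
      warning(sprintf("p = %.2f skipped: split too small", p))
      return(NULL)
    }
    data.frame(p = p, R2 = res$R2, r = res$r)
  })
  sweep <- do.call(rbind, rows)
  if (is.null(sweep) || !nrow(sweep))
    stop("every proportion in pGrid yielded an unusable split")
  sel <- selectRepOptimal(sweep)
  model <- fitAt(sel$p)$model
  list(model = model, p = sel$p, sweep = sel$sweep, tolerance = tolerance,
       design = des)
}

#' Fill missing RA records with a fitted imputation model
#'
#' Every missing RA cell (grades 2+) whose predictors are available is
#' replaced by the model prediction; observed cells are untouched. Filled
#' cells are flagged in `metadata(x)$imputedRA` (a logical matrix) and
#' counted in `metadata(x)$imputationLog`; rows with insufficient
#' predictors are left missing and logged.
#'
#' @param cohort a [MyopiaCohort-class] with missing RA cells.
#' @param model a [GbrtModel-class] from [selectImputationModel()].
#' @param factors the predictor factors the model was trained with.
#' @return the cohort with RA filled.
#' @export
fillMissing <- function(cohort, model, factors) {
  if (is(factors, "FeatureSubset")) factors <- subsetFactors(factors)
  des <- .imputationDesign(cohort, factors)
  ra <- assay(cohort, "RA")
  flag <- matrix(FALSE, nrow(ra), ncol(ra), dimnames = dimnames(ra))
  miss <- is.na(des$y)
  if (any(miss)) {
    pred <- gbrtPredict(model, des$X[miss, , drop = FALSE])
    idx <- cbind(match(des$student[miss], studentIds(cohort)),
                 match(des$grade[miss], gradeLevels(cohort)))
    ra[idx] <- pred
    flag[idx] <- TRUE
  }
  assay(cohort, "RA") <- ra
  unfillable <- sum(is.na(ra))
  metadata(cohort)$imputedRA <- flag
  metadata(cohort)$imputationLog <- list(
    filled = sum(flag), leftMissing = unfillable,
    skippedStudents = des$skipped)
  if (unfillable > 0)
    warning(sprintf("%d RA cell(s) left missing (predictors unavailable)",
                    unfillable))
  cohort
}
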