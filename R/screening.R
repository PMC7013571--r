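#' Univariate correlation screen
#'
#' Pearson correlation between each candidate factor (reduced to one value
#' per student) and the target, with a two-sided p-value from
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom. For a binary
#' target this is the point-biserial correlation. Zero-variance factors are
#' reported with correlation 0 and p = 1.
#'
#' @param features numeric matrix (students x factors) of reduced values, or
#'   a [MyopiaCohort-class] (reduced with [studentFeatures()],
#'   available-case).
#' @param target numeric or binary vector, one value per student,
#'   non-constant.
#' @return data.frame with columns `factor`, `correlation`, `p_value`.
#' @export
univariateScreen <- function(features, target) {
  if (is(features, "MyopiaCohort"))
    features <- studentFeatures(features, availableCase = TRUE)
  features <- as.matrix(features)
  ok <- complete.cases(features) & !is.na(target)
  features <- features[ok, , drop = FALSE]
  target <- as.numeric(target[ok])
  n <- length(target)
  if (n < 3) stop("univariate screening needs at least 3 students")
  if (sd(target) == 0) stop("target is constant")
  res <- lapply(colnames(features), function(nm) {
    x <- features[, nm]
    if (sd(x) == 0)
      return(data.frame(factor = nm, correlation = 0, p_value = 1))
    r <- cor(x, target)
    r <- max(min(r, 1), -1)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 0))
    p <- if (is.infinite(tstat)) 0 else 2 * pt(-abs(tstat), df = n - 2)
    data.frame(factor = nm, correlation = r, p_value = p)
  })
  do.call(rbind, res)
}

#' Preliminary subset from the univariate screen
#'
#' Keeps the factors whose p-value is strictly below `alpha`, preserving the
#' original order. Alternatively `topK` selects the `topK` smallest
#' p-values regardless of `alpha` (the "univariate only" wide variant).
#'
#' @param results data.frame from [univariateScreen()].
#' @param alpha significance level in (0, 1).
#' @param topK optional count overriding the alpha rule.
#' @return a [FeatureSubset-class] with provenance `"univariate"`. An empty
#'   survivor set is returned (with a warning), not an error.
#' @export
selectPreliminary <- function(results, alpha = 0.05, topK = NULL) {
  stopifnot(alpha >= 0, alpha < 1)
  if (!is.null(topK)) {
    ord <- order(results$p_value)
    keep <- results$factor[ord[seq_len(min(topK, nrow(results)))]]
    keep <- results$factor[results$factor %in% keep]  # original order
  } else {
    keep <- results$factor[results$p_value < alpha]
  }
  if (!length(keep)) warning("no factor survived the univariate screen")
  FeatureSubset(keep, rep("univariate", length(keep)))
}

#' Multivariate linear-regression refit of the preliminary subset
#'
#' Ordinary least squares of the target on all surviving factors jointly,
#' reporting per-coefficient standard errors, t statistics and two-sided
#' p-values on n-k-1 degrees of freedom. Collinear columns are dropped with
#' a warning naming them.
#'
#' @param features reduced-value matrix or [MyopiaCohort-class] as in
#'   [univariateScreen()].
#' @param subset a [FeatureSubset-class] (or character vector).
#' @param target as in [univariateScreen()].
#' @return data.frame with columns `factor`, `coefficient`, `std_err`,
#'   `t_stat`, `p_value`.
#' @export
multivariateFit <- function(features, subset, target) {
  if (is(features, "MyopiaCohort"))
    features <- studentFeatures(features, availableCase = TRUE)
  factors <- if (is(subset, "FeatureSubset")) subsetFactors(subset)
             else as.character(subset)
  features <- as.matrix(features)[, factors, drop = FALSE]
  ok <- complete.cases(features) & !is.na(target)
  features <- features[ok, , drop = FALSE]
  target <- as.numeric(target[ok])
  if (length(target) <= length(factors) + 1)
    stop("need more students than factors + 1 for the multivariate fit")
  df <- data.frame(.y = target, features, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients
  aliased <- setdiff(factors, sub("^`|`$", "", rownames(cf)))
  if (length(aliased))
    warning(sprintf("collinear factor(s) dropped: %s",
                    paste(aliased, collapse = ", ")))
  kept <- setdiff(factors, aliased)
  rn <- sub("^`|`$", "", rownames(cf))
  idx <- match(kept, rn)
  data.frame(factor = kept, coefficient = cf[idx, 1], std_err = cf[idx, 2],
             t_stat = cf[idx, 3], p_value = cf[idx, 4],
             row.names = NULL)
}

#' Final feature subset from the multivariate analysis
#'
#' Keeps factors with multivariate p-value strictly below `alpha` and
#' appends the forced factors (RA conventionally, since diopter history is a
#' key predictor regardless of its regression p-value). A forced factor that
#' already survived keeps provenance `"multivariate"` and appears once.
#'
#' @param results data.frame from [multivariateFit()].
#' @param alpha significance level in (0, 1).
#' @param forced character vector of factors to force in.
#' @return a [FeatureSubset-class].
#' @export
selectFinal <- function(results, alpha = 0.05, forced = "RA") {
  stopifnot(alpha >= 0, alpha < 1)
  keep <- results$factor[results$p_value < alpha]
  prov <- rep("multivariate", length(keep))
  extra <- setdiff(forced, keep)
  FeatureSubset(c(keep, extra),
                c(prov, rep("forced", length(extra))))
}

#' Two-stage feature selection in one call
#'
#' Runs [univariateScreen()], [selectPreliminary()], [multivariateFit()] and
#' [selectFinal()] on a cohort and target, returning all intermediate
#' tables.
#'
#' @inheritParams univariateScreen
#' @param candidates factors to screen (default: all non-RA factors).
#' @param alpha significance level for both stages.
#' @param forced factors forced into the final subset.
#' @return list with `univariate`, `preliminary`, `multivariate`, `final`.
#' @export
screenFactors <- function(features, target,
                          candidates = NULL, alpha = 0.05, forced = "RA") {
  if (is(features, "MyopiaCohort")) {
    if (is.null(candidates))
      candidates <- setdiff(factorNames(features), "RA")
    features <- studentFeatures(features, factors = candidates,
                                availableCase = TRUE)
  } else if (!is.null(candidates)) {
    features <- features[, candidates, drop = FALSE]
  }
  uni <- univariateScreen(features, target)
  prelim <- selectPreliminary(uni, alpha)
  if (!length(prelim)) {
    return(list(univariate = uni, preliminary = prelim,
                multivariate = NULL,
                final = selectFinal(data.frame(factor = character(),
                                               p_value = numeric()),
                                    alpha, forced)))
  }
  multi <- multivariateFit(features, prelim, target)
  list(univariate = uni, preliminary = prelim, multivariate = multi,
       final = selectFinal(multi, alpha, forced))
}
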