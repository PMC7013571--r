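#' Clean a cohort: range rules and whole-student exclusions
#'
#' Applies per-factor admissible ranges (out-of-range cells become missing)
#' and drops flagged students entirely (e.g. congenital amblyopia or ocular
#' defects). Removal counts are logged in `metadata(x)$cleaning`.
#'
#' @param cohort a [MyopiaCohort-class].
#' @param rules list with components `ranges` (named list of `c(min, max)`
#'   per factor; default confines RA to [-12, 8] D) and `excludeStudents`
#'   (character ids to drop).
#' @return the cleaned cohort.
#' @export
cleanRecords <- function(cohort,
                         rules = list(ranges = list(RA = c(-12, 8)),
                                      excludeStudents = character())) {
  ranges <- rules$ranges
  excl <- rules$excludeStudents
  if (is.null(excl)) excl <- character()
  counts <- setNames(integer(length(ranges)), names(ranges))
  for (nm in names(ranges)) {
    if (!nm %in% factorNames(cohort)) next
    m <- assay(cohort, nm)
    bad <- !is.na(m) & (m < ranges[[nm]][1] | m > ranges[[nm]][2])
    counts[nm] <- sum(bad)
    m[bad] <- NA_real_
    assay(cohort, nm) <- m
  }
  dropped <- intersect(excl, studentIds(cohort))
  if (length(dropped))
    cohort <- cohort[!studentIds(cohort) %in% dropped, ]
  metadata(cohort)$cleaning <- list(outOfRange = counts,
                                    droppedStudents = dropped)
  cohort
}

#' Longitudinal reducers: annual progress, sum, mean
#'
#' The factor-type-specific reductions that turn a grade 1-5 series into one
#' feature per student: `annualProgressFeature` averages consecutive-grade
#' differences of RA (next minus previous, so negative values mean myopic
#' progression; with all five grades observed this telescopes to
#' `(RA5 - RA1)/4`); `sumFeature` totals behaviour/diet frequencies;
#' `meanFeature` averages continuous ocular measurements.
#'
#' @param series numeric vector over grades (1-5 normally); `NA` = missing.
#' @return a single numeric value.
#' @examples
#' annualProgressFeature(c(0, -0.5, -1, -1.5, -2))  # -0.5
#' sumFeature(c(2, 0, 3, 1, 1))                     # 7
#' meanFeature(c(22, 22.5, 23, 23.5, 24))           # 23
#' @export
annualProgressFeature <- function(series) {
  obs <- which(!is.na(series))
  if (length(obs) < 2)
    stop("annual progress needs at least 2 observed grades")
  d <- diff(series)
  d <- d[!is.na(d)]  # consecutive pairs with both grades observed
  if (length(d)) mean(d)
  else  # no consecutive pair: slope over the observed span
    (series[max(obs)] - series[min(obs)]) / (max(obs) - min(obs))
}

#' @rdname annualProgressFeature
#' @export
sumFeature <- function(series) {
  if (anyNA(series))
    stop(sprintf("missing value(s) at grade(s) %s",
                 paste(which(is.na(series)), collapse = ", ")))
  sum(series)
}

#' @rdname annualProgressFeature
#' @export
meanFeature <- function(series) sumFeature(series) / length(series)

#' Reduce a cohort to one value per student per factor
#'
#' Applies each factor's transform rule over the feature grades (1-5 by
#' default; grade 6 is reserved for the outcome): `passthrough` takes the
#' grade-1 value, `sum` and `mean` aggregate, `annual_progress` averages
#' consecutive differences. With `availableCase = TRUE`, incomplete series
#' are reduced from the observed grades only (sums rescaled by
#' `nGrades/nObserved`), which the screening stage uses before imputation;
#' otherwise missing entries raise an error.
#'
#' @param cohort a [MyopiaCohort-class].
#' @param factors factor names to reduce (default all).
#' @param grades grades to reduce over, default `1:5` intersected with the
#'   cohort's grades.
#' @param availableCase reduce from observed grades instead of erroring.
#' @return numeric matrix, students x factors; `NA` where a student has no
#'   usable value under `availableCase`.
#' @export
studentFeatures <- function(cohort, factors = factorNames(cohort),
                            grades = NULL, availableCase = FALSE) {
  gl <- gradeLevels(cohort)
  if (is.null(grades)) grades <- gl[gl <= gl[1] + 4]
  gi <- match(grades, gl)
  fi <- factorInfo(cohort)
  out <- matrix(NA_real_, nrow(cohort), length(factors),
                dimnames = list(studentIds(cohort), factors))
  for (nm in factors) {
    m <- assay(cohort, nm)[, gi, drop = FALSE]
    rule <- fi$transform_rule[fi$name == nm]
    out[, nm] <- switch(rule,
      passthrough = m[, 1],
      sum = if (availableCase) {
        k <- rowSums(!is.na(m))
        ifelse(k > 0, rowSums(m, na.rm = TRUE) * ncol(m) / k, NA_real_)
      } else apply(m, 1, sumFeature),
      mean = if (availableCase) rowMeans(m, na.rm = TRUE)
             else apply(m, 1, meanFeature),
      annual_progress = apply(m, 1, function(s) {
        if (sum(!is.na(s)) < 2) {
          if (availableCase) return(NA_real_)
          stop(sprintf("factor %s: fewer than 2 observed grades", nm))
        }
        annualProgressFeature(s)
      }),
      stop(sprintf("unknown transform rule '%s' for factor %s", rule, nm)))
  }
  out
}

#' Build the normalized per-student feature matrix
#'
#' Reduces the selected factors (grades 1-5) with their transform rules and
#' min-max normalizes each feature to [0, 1]. Normalization statistics are
#' learned on the training rows only and applied to all rows; a degenerate
#' feature (min = max on the training rows) maps to 0.
#'
#' @param cohort a complete-for-grades-1-5 [MyopiaCohort-class]
#'   (post-imputation).
#' @param subset a [FeatureSubset-class] (or character vector) of factors.
#' @param labels named binary outcome vector (see [deriveMyopiaLabel()]);
#'   students absent from `labels` are dropped.
#' @param trainIds student ids on which to fit the normalization (default:
#'   all labeled students).
#' @param normalize set `FALSE` to keep raw reduced values.
#' @return a [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(cohort, subset, labels,
                               trainIds = NULL, normalize = TRUE) {
  factors <- if (is(subset, "FeatureSubset")) subsetFactors(subset)
             else as.character(subset)
  keep <- intersect(studentIds(cohort), names(labels))
  cohort <- cohort[keep, ]
  raw <- studentFeatures(cohort, factors)
  if (is.null(trainIds)) trainIds <- rownames(raw)
  trainIds <- intersect(trainIds, rownames(raw))
  if (normalize) {
    mins <- apply(raw[trainIds, , drop = FALSE], 2, min)
    maxs <- apply(raw[trainIds, , drop = FALSE], 2, max)
    rng <- maxs - mins
    vals <- sweep(raw, 2, mins)
    vals <- sweep(vals, 2, ifelse(rng > 0, rng, 1), "/")
    vals[, rng == 0] <- 0  # degenerate feature: constant on training rows
  } else {
    mins <- rep(0, ncol(raw)); maxs <- rep(1, ncol(raw))
    vals <- raw
  }
  new("FeatureMatrix", values = vals,
      label = as.numeric(labels[rownames(vals)]),
      normParams = data.frame(feature = factors, min = unname(mins),
                              max = unname(maxs)),
      trainIds = trainIds)
}

#' Undo min-max normalization of a feature matrix
#'
#' @param fm a [FeatureMatrix-class].
#' @return the raw reduced-value matrix.
#' @export
denormalizeFeatures <- function(fm) {
  p <- normParams(fm)
  rng <- p$max - p$min
  raw <- sweep(featureValues(fm), 2, ifelse(rng > 0, rng, 1), "*")
  raw <- sweep(raw, 2, p$min, "+")
  # degenerate columns carry no information; restore the constant
  raw[, rng == 0] <- matrix(p$min[rng == 0], nrow(raw),
                            sum(rng == 0), byrow = TRUE)
  raw
}

# Fill residual missing cells of non-RA factors: the student's own mean over
# observed grades, falling back to the per-grade cohort median. The GBRT
# imputer handles RA; other factors get this simple deterministic fill.
fillFactorCells <- function(cohort) {
  for (nm in setdiff(factorNames(cohort), "RA")) {
    m <- assay(cohort, nm)
    if (!anyNA(m)) next
    rowMean <- rowMeans(m, na.rm = TRUE)
    colMed <- apply(m, 2, median, na.rm = TRUE)
    for (g in seq_len(ncol(m))) {
      idx <- is.na(m[, g])
      m[idx, g] <- rowMean[idx]
      still <- is.na(m[, g])
      m[still, g] <- colMed[g]
    }
    assay(cohort, nm) <- m
  }
  cohort
}
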