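#' Simulate a complete longitudinal myopia cohort
#'
#' Generates a [MyopiaCohort-class] with no missing cells under a
#' linear-Gaussian progression model. Each student i receives a latent annual
#' RA progression
#' \deqn{\Delta_i = drift - noiseSd \sum_k e_k z_{ik},}
#' where \eqn{z_{ik}} is the student's standardized reduced value of factor k
#' (reduced over grades 1-5 by the factor's transform rule) and \eqn{e_k} the
#' configured signed effect. RA is then measured per grade around the linear
#' trend: \eqn{RA_{i,1} \sim N(baselineMean, baselineSd^2)} and for g > 1
#' \eqn{RA_{i,g} = RA_{i,1} + (g-1)\Delta_i + \epsilon_{i,g}} with iid
#' measurement noise of SD `noiseSd` (grade 1 is measured exactly). Negative
#' effects therefore slow myopic progression (protective factors), positive
#' effects accelerate it (risk factors).
#'
#' @param config a [cohortConfig()] object.
#' @return a complete [MyopiaCohort-class]; `rowData` carries `gender`.
#' @examples
#' coh <- simulateCohort(cohortConfig(nStudents = 50, seed = 1))
#' coh
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "CohortConfig"))
    config <- do.call(cohortConfig, config)
  set.seed(config$seed)
  n <- config$nStudents
  grades <- config$grades
  G <- length(grades)
  fs <- config$factorSet
  ids <- sprintf("S%05d", seq_len(n))

  gender <- rbinom(n, 1, config$maleFraction)
  vals <- list()
  for (k in seq_len(nrow(fs))) {
    nm <- fs$name[k]
    if (nm == "RA") { vals[[nm]] <- NULL; next }
    kind <- fs$kind[k]
    m <- matrix(NA_real_, n, G)
    if (kind == "objective") {
      v <- if (nm == "GENDER") gender
           else if (nm == "DAI") sample(0:2, n, replace = TRUE,
                                        prob = c(0.45, 0.40, 0.15))
           else sample(seq_len(max(fs$gen_levels[k], 2, na.rm = TRUE)) - 1,
                       n, replace = TRUE)
      m[] <- v  # time-invariant, replicated across grades
    } else if (kind == "continuous_ocular") {
      u <- rnorm(n)
      for (g in seq_len(G))
        m[, g] <- fs$gen_mean[k] + fs$gen_sd[k] * u +
          0.3 * fs$gen_sd[k] * rnorm(n)
    } else {  # categorical_behavioral: ordinal 0..L-1, grade-varying
      L <- fs$gen_levels[k]
      if (is.na(L)) L <- 4
      u <- rnorm(n)
      cuts <- qnorm(seq_len(L - 1) / L)
      for (g in seq_len(G)) {
        lat <- 0.8 * u + 0.6 * rnorm(n)
        m[, g] <- findInterval(lat, cuts)
      }
    }
    vals[[nm]] <- m
  }

  # standardized reduced factor values drive the planted progression effects
  eff <- config$effectSizes
  eff <- eff[names(eff) != "RA"]
  delta <- rep(config$driftPerYear, n)
  if (length(eff)) {
    red <- vapply(names(eff), function(nm) {
      m <- vals[[nm]][, seq_len(min(5, G)), drop = FALSE]
      rule <- fs$transform_rule[fs$name == nm]
      switch(rule,
             passthrough = m[, 1],
             sum = rowSums(m),
             mean = rowMeans(m),
             stop(sprintf("no reduction for rule '%s'", rule)))
    }, numeric(n))
    z <- apply(red, 2, function(v) {
      s <- sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    delta <- delta - config$noiseSd * drop(z %*% eff)
  }

  ra <- matrix(NA_real_, n, G)
  ra[, 1] <- config$baselineMean + config$baselineSd * rnorm(n)
  for (g in 2:G)
    ra[, g] <- ra[, 1] + (g - 1) * delta + config$noiseSd * rnorm(n)
  ra <- pmin(pmax(ra, config$raRange[1]), config$raRange[2])
  vals$RA <- ra

  vals <- vals[fs$name]
  coh <- MyopiaCohort(vals, fs[, c("name", "description", "kind",
                                   "transform_rule")],
                      grades = grades, studentIds = ids)
  rowData(coh)$gender <- gender
  metadata(coh)$config <- config
  coh
}

#' Introduce grade-biased missingness into a complete cohort
#'
#' Cells are set missing at random conditional on grade only. The diopter
#' record RA follows a grade-increasing schedule -- grade 1 fully observed,
#' rising linearly to `missingRateMax` at the final grade (senior-grade
#' diopter data are the least complete). All other factors follow a flat
#' schedule over grades 2+ calibrated so their overall per-factor missing
#' rate equals `missingRateMean` (grade 1 stays complete for every factor).
#'
#' @param cohort a complete [MyopiaCohort-class].
#' @param config the [cohortConfig()] that produced it (rates and seed are
#'   read from it), or `NULL` to use `missingRateMean`/`missingRateMax`/
#'   `seed` directly.
#' @param missingRateMean,missingRateMax,seed overrides when `config` is
#'   `NULL`.
#' @return the cohort with `NA` cells; the applied per-grade schedules are
#'   stored in `metadata(x)$missingSchedule`.
#' @export
applyMissingness <- function(cohort, config = metadata(cohort)$config,
                             missingRateMean = 0.15, missingRateMax = 0.40,
                             seed = 1) {
  if (!is.null(config)) {
    missingRateMean <- config$missingRateMean
    missingRateMax <- config$missingRateMax
    seed <- deriveSeed(config$seed, "missingness")
  }
  if (missingRateMean < 0 || missingRateMax > 1 ||
      missingRateMean > missingRateMax)
    stop("invalid configuration: missing rates must satisfy ",
         "0 <= mean <= max <= 1")
  grades <- gradeLevels(cohort)
  G <- length(grades)
  rel <- (grades - grades[1]) / (grades[G] - grades[1])
  raRate <- missingRateMax * rel                      # 0 at grade 1
  flatRate <- c(0, rep(min(1, missingRateMean * G / (G - 1)), G - 1))
  set.seed(seed)
  for (nm in factorNames(cohort)) {
    rate <- if (nm == "RA") raRate else flatRate
    m <- assay(cohort, nm)
    for (g in seq_len(G))
      if (rate[g] > 0)
        m[runif(nrow(m)) < rate[g], g] <- NA_real_
    assay(cohort, nm) <- m
  }
  metadata(cohort)$missingSchedule <- list(RA = raRate, other = flatRate)
  cohort
}

#' Derive the binary grade-6 myopia label
#'
#' A student is labeled myopic (1) when the final-grade RA is at or below
#' `threshold` diopters (boundary inclusive; negative diopters = myopic).
#' The conventional spherical-equivalent cutoff of -0.5 D is the default.
#'
#' @param cohort a [MyopiaCohort-class] whose final-grade RA is observed for
#'   every student (normally post-imputation).
#' @param threshold diopter cutoff, default -0.5.
#' @param grade grade at which to label; defaults to the final grade.
#' @return named integer vector (0/1) over students.
#' @export
deriveMyopiaLabel <- function(cohort, threshold = -0.5,
                              grade = max(gradeLevels(cohort))) {
  ra <- assay(cohort, "RA")[, match(grade, gradeLevels(cohort))]
  if (anyNA(ra)) {
    bad <- studentIds(cohort)[is.na(ra)]
    stop(sprintf(
      "grade-%d RA missing for %d student(s): %s%s", grade, length(bad),
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""))
  }
  setNames(as.integer(ra <= threshold), studentIds(cohort))
}
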