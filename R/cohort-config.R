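#' Default factor panel for cohort simulation
#'
#' The 25 candidate factors routinely screened in school-myopia studies
#' (parental myopia, gender, accommodation, visual acuity, activity, axial
#' length, keratometry, pulse, tutoring, screen/reading habits, diet, ...)
#' plus the diopter record RA. Each factor carries its kind, its longitudinal
#' transform rule, a default signed effect size on annual RA progression
#' (standardized units; negative = protective, positive = risk; zero for the
#' nuisance factors) and the marginal-distribution parameters used by
#' [simulateCohort()].
#'
#' @param nNuisance number of additional named zero-effect nuisance factors
#'   (`NUIS001`, ...), alternating behavioral/ocular kinds, emulating the
#'   "wide" regime where most collected factors are irrelevant.
#' @return data.frame with columns `name`, `description`, `kind`,
#'   `transform_rule`, `effect`, `gen_mean`, `gen_sd`, `gen_levels`.
#' @export
defaultFactorSet <- function(nNuisance = 0) {
  f <- function(name, description, kind, effect, gen_mean = NA,
                gen_sd = NA, gen_levels = NA)
    data.frame(name = name, description = description, kind = kind,
               transform_rule = unname(.kindRule[kind]), effect = effect,
               gen_mean = gen_mean, gen_sd = gen_sd, gen_levels = gen_levels,
               stringsAsFactors = FALSE)
  fi <- rbind(
    f("DAI",     "No. of parents wearing glasses",   "objective", -0.35,
      gen_levels = 3),
    f("GENDER",  "Gender (1 = male)",                "objective", -0.30,
      gen_levels = 2),
    f("RPR",     "Refraction before mydriasis",      "continuous_ocular",
      0.00, 0.75, 0.50),
    f("JTR",     "Close adjustment ability",         "continuous_ocular",
      0.40, 4.50, 1.20),
    f("YTR",     "Remote adjustment ability",        "continuous_ocular",
      0.55, 5.50, 1.50),
    f("DRNBASE", "Distant vision",                   "continuous_ocular",
      0.00, 4.90, 0.25),
    f("JG",      "Amount of indoor activities",      "categorical_behavioral",
      -0.40, gen_levels = 4),
    f("YW",      "Amount of outdoor activities",     "categorical_behavioral",
      -0.35, gen_levels = 4),
    f("AL",      "Axial length (mm)",                "continuous_ocular",
      -0.50, 23.5, 0.90),
    f("K1",      "Corneal curvature (left eye)",     "continuous_ocular",
      -0.35, 43.0, 1.50),
    f("K2",      "Corneal curvature (right eye)",    "continuous_ocular",
      -0.35, 42.5, 1.50),
    f("PULSE",   "Pulses per minute",                "continuous_ocular",
      0.45, 85.0, 10.0),
    f("TUTOR1",  "Participation in outdoor classes", "categorical_behavioral",
      0.00, gen_levels = 4),
    f("TUTOR2",  "Participation in indoor classes",  "categorical_behavioral",
      0.00, gen_levels = 4),
    f("ETEST",   "Regular eye examination",          "categorical_behavioral",
      0.00, gen_levels = 2),
    f("MSMK",    "Exposure to smoking",              "categorical_behavioral",
      0.00, gen_levels = 2),
    f("CELLP",   "Plays cellphone",                  "categorical_behavioral",
      0.00, gen_levels = 2),
    f("COSTM",   "Writes with wrong posture",        "categorical_behavioral",
      0.00, gen_levels = 2),
    f("BED",     "Reads in bed",                     "categorical_behavioral",
      0.00, gen_levels = 2),
    f("COLA",    "Carbonated drink frequency",       "categorical_behavioral",
      0.40, gen_levels = 4),
    f("REDM",    "Red meat frequency",               "categorical_behavioral",
      0.35, gen_levels = 4),
    f("WHIM",    "White meat frequency",             "categorical_behavioral",
      -0.30, gen_levels = 4),
    f("EGG",     "Egg frequency",                    "categorical_behavioral",
      -0.35, gen_levels = 4),
    f("MILK",    "Milk frequency",                   "categorical_behavioral",
      0.00, gen_levels = 4),
    f("VOLUME",  "Daily water intake",               "categorical_behavioral",
      0.00, gen_levels = 4),
    f("RA",      "Refraction (diopters)",            "diopter", 0.00))
  if (nNuisance > 0) {
    kinds <- rep(c("categorical_behavioral", "continuous_ocular"),
                 length.out = nNuisance)
    nf <- do.call(rbind, lapply(seq_len(nNuisance), function(i) {
      if (kinds[i] == "continuous_ocular")
        f(sprintf("NUIS%03d", i), "Nuisance factor", kinds[i], 0, 0, 1)
      else
        f(sprintf("NUIS%03d", i), "Nuisance factor", kinds[i], 0,
          gen_levels = 4)
    }))
    fi <- rbind(fi, nf)
  }
  fi
}

#' Configuration for cohort simulation
#'
#' Validates and bundles the parameters of the generative model. The default
#' values emulate the documented shape of a multi-school primary cohort:
#' 3112 students, 57.8% male, grades 1-6, ~15% mean per-factor missingness
#' with a 40% maximum (diopter data worst in the senior grades, grade 1
#' complete).
#'
#' Effect sizes are standardized: one standard deviation of a factor's
#' reduced (grade 1-5) value shifts annual RA progression by
#' `effect * noiseSd` diopters per year, negative effects slowing myopic
#' progression (protective) and positive effects accelerating it (risk).
#'
#' @param nStudents cohort size (>= 1).
#' @param maleFraction proportion of male students in [0, 1].
#' @param grades inclusive grade range, default `1:6`.
#' @param factorSet factor panel as returned by [defaultFactorSet()].
#' @param effectSizes named numeric vector of signed standardized effects;
#'   default taken from `factorSet$effect`.
#' @param noiseSd per-grade measurement noise SD of RA, diopters.
#' @param baselineMean,baselineSd grade-1 RA distribution, diopters.
#' @param driftPerYear population mean annual RA progression, diopters/year
#'   (negative = myopic drift).
#' @param missingRateMean,missingRateMax target mean and maximum per-factor
#'   missing rates; `0 <= mean <= max <= 1`.
#' @param raRange plausible diopter interval; simulated RA is clamped to it.
#' @param seed integer seed making the simulation deterministic.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nStudents = 3112, maleFraction = 0.578,
                         grades = 1:6, factorSet = defaultFactorSet(),
                         effectSizes = NULL, noiseSd = 0.25,
                         baselineMean = 0.5, baselineSd = 0.75,
                         driftPerYear = -0.15, missingRateMean = 0.15,
                         missingRateMax = 0.40, raRange = c(-12, 8),
                         seed = 1) {
  chk <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid configuration: %s %s", field, what),
                  call. = FALSE)
  }
  chk(is.numeric(nStudents) && nStudents >= 1, "nStudents", "must be >= 1")
  chk(is.numeric(maleFraction) && maleFraction >= 0 && maleFraction <= 1,
      "maleFraction", "must lie in [0, 1]")
  chk(is.numeric(noiseSd) && noiseSd >= 0, "noiseSd", "must be >= 0")
  chk(missingRateMean >= 0 && missingRateMean <= 1,
      "missingRateMean", "must lie in [0, 1]")
  chk(missingRateMax >= 0 && missingRateMax <= 1,
      "missingRateMax", "must lie in [0, 1]")
  chk(missingRateMean <= missingRateMax,
      "missingRateMean", "must not exceed missingRateMax")
  chk(length(grades) >= 2 && all(diff(grades) == 1),
      "grades", "must be a consecutive integer range")
  chk(is.data.frame(factorSet) && "RA" %in% factorSet$name,
      "factorSet", "must be a data.frame containing an RA factor")
  chk(raRange[1] < raRange[2], "raRange", "must be an increasing interval")
  if (is.null(effectSizes))
    effectSizes <- setNames(factorSet$effect, factorSet$name)
  unknown <- setdiff(names(effectSizes), factorSet$name)
  chk(length(unknown) == 0, "effectSizes",
      sprintf("names unknown factors: %s", paste(unknown, collapse = ", ")))
  structure(list(
    nStudents = as.integer(nStudents), maleFraction = maleFraction,
    grades = as.integer(grades), factorSet = factorSet,
    effectSizes = effectSizes, noiseSd = noiseSd,
    baselineMean = baselineMean, baselineSd = baselineSd,
    driftPerYear = driftPerYear, missingRateMean = missingRateMean,
    missingRateMax = missingRateMax, raRange = raRange,
    seed = as.integer(seed)), class = "CohortConfig")
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf(
    "CohortConfig: n = %d, male %.1f%%, grades %d-%d, %d factors, seed %d\n",
    x$nStudents, 100 * x$maleFraction, min(x$grades), max(x$grades),
    nrow(x$factorSet), x$seed))
  cat(sprintf(
    "  RA: baseline %.2f (sd %.2f) D, drift %.2f D/yr, noise sd %.2f D\n",
    x$baselineMean, x$baselineSd, x$driftPerYear, x$noiseSd))
  cat(sprintf("  missingness: mean %.2f, max %.2f\n",
              x$missingRateMean, x$missingRateMax))
  invisible(x)
}

# Deterministic per-stage seed derived from a master seed; keeps all derived
# seeds below 2^31.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
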