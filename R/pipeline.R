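#' Configure an end-to-end pipeline run
#'
#' One master seed drives every stage (per-stage seeds are derived from it
#' by stage-name hashing), so a run is fully reproducible and each stage can
#' be re-run independently.
#'
#' @param cohort an existing [MyopiaCohort-class], or `NULL` to simulate.
#' @param cohort_config a [cohortConfig()] used when `cohort` is `NULL`;
#'   missingness is applied per its rates.
#' @param alpha significance level for both screening stages.
#' @param forced factors forced into the final subset (default RA).
#' @param labelThreshold diopter cutoff for the grade-6 myopia label.
#' @param tolerance imputation error range y, diopters.
#' @param pGrid train proportions for the imputation sweep.
#' @param gbrt list of GBRT hyper-parameters (`rounds`, `shrinkage`,
#'   `maxDepth`, `minLeaf`).
#' @param model list with SVM penalty `C`, decision `threshold`, CV `folds`.
#' @param baselines baseline methods for the comparison table
#'   (`character()` to skip).
#' @param cleanRules rules for [cleanRecords()].
#' @param outDir directory for stage outputs (`NULL` = nothing written).
#' @param nested re-run selection and imputation inside each CV fold
#'   (leakage-free evaluation) instead of the default
#'   select/impute-then-evaluate order.
#' @param seed master seed.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(cohort = NULL, cohort_config = cohortConfig(),
                           alpha = 0.05, forced = "RA",
                           labelThreshold = -0.5, tolerance = 0.5,
                           pGrid = seq(0.1, 0.9, 0.1),
                           gbrt = list(rounds = 100, shrinkage = 0.1,
                                       maxDepth = 3, minLeaf = 5),
                           model = list(C = 1.0, threshold = 0.5,
                                        folds = 10),
                           baselines = character(),
                           cleanRules = list(ranges = list(RA = c(-12, 8)),
                                             excludeStudents = character()),
                           outDir = NULL, nested = FALSE, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, tolerance > 0,
            all(pGrid > 0 & pGrid < 1), model$C > 0,
            model$threshold > 0, model$threshold < 1, model$folds >= 2)
  structure(list(cohort = cohort, cohort_config = cohort_config,
                 alpha = alpha, forced = forced,
                 labelThreshold = labelThreshold, tolerance = tolerance,
                 pGrid = pGrid, gbrt = gbrt, model = model,
                 baselines = baselines, cleanRules = cleanRules,
                 outDir = outDir, nested = nested, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.writeOut <- function(obj, outDir, name, writer) {
  if (is.null(outDir)) return(NULL)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  path <- file.path(outDir, name)
  writer(obj, path)
  path
}

#' Run the three-phase prediction pipeline
#'
#' Factor Selection (two-stage correlation screening) -> Data Curation
#' (clean, REP-selected GBRT imputation of RA, simple fill of other
#' factors, factor-type transforms, min-max normalization) -> Model
#' Construction (linear SVM on a stratified 80/20 holdout, k-fold CV and
#' optional baseline comparison). All intermediate tables are written to
#' `config$outDir` when set, and a manifest records seeds, timings, file
#' digests, the selected features, the chosen train proportion and all
#' warnings.
#'
#' @param config a [pipelineConfig()].
#' @return a `myoPipelineRun` list: `manifest`, `cohort`, `screen`,
#'   `subset`, `imputation`, `featureMatrix`, `report`
#'   ([EvalReport-class]), `baselines`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[3]
  warnings <- character()
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  timings <- c()
  stamp <- function(stage) {
    timings[stage] <<- proc.time()[3] - t0
    t0 <<- proc.time()[3]
  }
  files <- list()

  # -- cohort -----------------------------------------------------------
  cohort <- config$cohort
  if (is.null(cohort)) {
    cc <- config$cohort_config
    cc$seed <- deriveSeed(config$seed, "simulate")
    cohort <- grab(applyMissingness(simulateCohort(cc), cc))
  }
  cohort <- grab(cleanRecords(cohort, config$cleanRules))
  files$cohort <- .writeOut(cohort, config$outDir, "cohort_long.csv",
                            writeCohortCsv)
  files$factorInfo <- .writeOut(cohort, config$outDir, "factor_info.csv",
                                writeFactorInfo)
  stamp("cohort")

  if (config$nested)
    return(.runNestedPipeline(config, cohort, warnings, files, timings))

  # -- phase 1: factor selection (available-case, observed labels) ------
  ra6 <- assay(cohort, "RA")[, ncol(cohort)]
  labAvail <- setNames(as.integer(ra6 <= config$labelThreshold),
                       studentIds(cohort))
  labAvail <- labAvail[!is.na(ra6)]
  scr <- grab(screenFactors(cohort[names(labAvail), ], labAvail,
                            alpha = config$alpha, forced = config$forced))
  files$univariate <- .writeOut(scr$univariate, config$outDir,
                                "univariate.csv",
                                function(o, p) write.csv(o, p, row.names = FALSE))
  if (!is.null(scr$multivariate))
    files$multivariate <- .writeOut(scr$multivariate, config$outDir,
                                    "multivariate.csv",
                                    function(o, p) write.csv(o, p, row.names = FALSE))
  files$subset <- .writeOut(scr$final, config$outDir, "feature_subset.txt",
                            function(o, p) writeLines(subsetFactors(o), p))
  stamp("screening")

  # -- phase 2: data curation -------------------------------------------
  imp <- grab(selectImputationModel(
    cohort, scr$final, pGrid = config$pGrid, tolerance = config$tolerance,
    rounds = config$gbrt$rounds, shrinkage = config$gbrt$shrinkage,
    maxDepth = config$gbrt$maxDepth, minLeaf = config$gbrt$minLeaf,
    seed = deriveSeed(config$seed, "impute")))
  cohort <- grab(fillMissing(cohort, imp$model, scr$final))
  cohort <- fillFactorCells(cohort)
  files$sweep <- .writeOut(imp$sweep, config$outDir, "rep_sweep.csv",
                           function(o, p) write.csv(o, p, row.names = FALSE))
  files$filled <- .writeOut(cohort, config$outDir, "cohort_filled.csv",
                            writeCohortCsv)
  stamp("imputation")

  ra6 <- assay(cohort, "RA")[, ncol(cohort)]
  usable <- !is.na(ra6)
  if (!all(usable)) {
    warnings <- c(warnings, sprintf(
      "%d student(s) dropped: grade-%d RA unfillable", sum(!usable),
      max(gradeLevels(cohort))))
    cohort <- cohort[usable, ]
  }
  labels <- deriveMyopiaLabel(cohort, config$labelThreshold)

  holdFold <- .stratifiedFolds(labels, 5, deriveSeed(config$seed, "holdout"))
  trainIds <- studentIds(cohort)[holdFold != 1]
  fm <- grab(buildFeatureMatrix(cohort, scr$final, labels,
                                trainIds = trainIds))
  files$features <- .writeOut(
    data.frame(student_id = rownames(featureValues(fm)),
               featureValues(fm), label = featureLabels(fm),
               check.names = FALSE),
    config$outDir, "feature_matrix.csv",
    function(o, p) write.csv(o, p, row.names = FALSE))
  stamp("transform")

  # -- phase 3: model construction --------------------------------------
  X <- featureValues(fm); y <- featureLabels(fm)
  test <- holdFold == 1
  clf <- grab(trainClassifier(X[!test, , drop = FALSE], y[!test],
                              C = config$model$C,
                              seed = deriveSeed(config$seed, "svm")))
  pred <- predictLabels(clf, X[test, , drop = FALSE],
                        config$model$threshold)
  cv <- grab(kfoldCV(fm, k = config$model$folds, C = config$model$C,
                     threshold = config$model$threshold,
                     seed = deriveSeed(config$seed, "cv")))
  report <- grab(evalReport(y[test], pred$probability,
                            config$model$threshold, cv))
  files$roc <- .writeOut(rocPoints(report), config$outDir, "roc_points.csv",
                         function(o, p) write.csv(o, p, row.names = FALSE))
  baseTab <- NULL
  if (length(config$baselines)) {
    baseTab <- grab(runBaselines(fm, config$baselines,
                                 threshold = config$model$threshold,
                                 cvFolds = config$model$folds,
                                 seed = deriveSeed(config$seed, "baselines")))
    files$comparison <- .writeOut(baseTab, config$outDir, "comparison.csv",
                                  function(o, p) write.csv(o, p, row.names = FALSE))
  }
  stamp("modeling")

  files <- files[!vapply(files, is.null, logical(1))]
  manifest <- list(
    seed = config$seed,
    stageSeeds = vapply(c("simulate", "impute", "holdout", "svm", "cv",
                          "baselines"),
                        function(s) deriveSeed(config$seed, s), integer(1)),
    timings = timings,
    files = if (length(files))
      data.frame(name = names(files), path = unlist(files),
                 md5 = unname(tools::md5sum(unlist(files))),
                 row.names = NULL) else NULL,
    selectedFeatures = subsetFactors(scr$final),
    provenance = subsetProvenance(scr$final),
    chosenP = imp$p, tolerance = imp$tolerance,
    imputation = metadata(cohort)$imputationLog,
    warnings = warnings)
  structure(list(manifest = manifest, cohort = cohort, screen = scr,
                 subset = scr$final, imputation = imp, featureMatrix = fm,
                 report = report, baselines = baseTab),
            class = "myoPipelineRun")
}

# Leakage-free variant: selection, imputation-model fitting and
# normalization are re-run inside each fold on its training students only.
.runNestedPipeline <- function(config, cohort, warnings, files, timings) {
  grab <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  k <- config$model$folds
  ra6 <- assay(cohort, "RA")[, ncol(cohort)]
  # folds stratified on the observed-label students; unlabeled students are
  # always available as training-side records
  lab <- setNames(as.integer(ra6 <= config$labelThreshold),
                  studentIds(cohort))
  lab <- lab[!is.na(ra6)]
  fold <- .stratifiedFolds(lab, k, deriveSeed(config$seed, "cv"))
  truth <- prob <- numeric(0)
  for (f in seq_len(k)) {
    testIds <- names(lab)[fold == f]
    trainCoh <- cohort[setdiff(studentIds(cohort), testIds), ]
    trLab <- lab[intersect(names(lab), studentIds(trainCoh))]
    scr <- grab(screenFactors(trainCoh[names(trLab), ], trLab,
                              alpha = config$alpha,
                              forced = config$forced))
    imp <- grab(selectImputationModel(
      trainCoh, scr$final, pGrid = config$pGrid,
      tolerance = config$tolerance, rounds = config$gbrt$rounds,
      shrinkage = config$gbrt$shrinkage, maxDepth = config$gbrt$maxDepth,
      minLeaf = config$gbrt$minLeaf,
      seed = deriveSeed(config$seed, paste0("impute", f))))
    filled <- fillFactorCells(grab(fillMissing(cohort, imp$model,
                                               scr$final)))
    ids <- c(names(trLab), testIds)
    labs <- lab[ids]
    fm <- grab(buildFeatureMatrix(filled[ids, ], scr$final, labs,
                                  trainIds = names(trLab)))
    X <- featureValues(fm)
    clf <- grab(trainClassifier(X[names(trLab), , drop = FALSE],
                                labs[names(trLab)], C = config$model$C,
                                seed = deriveSeed(config$seed,
                                                  paste0("svm", f))))
    pr <- predictLabels(clf, X[testIds, , drop = FALSE],
                        config$model$threshold)
    truth <- c(truth, labs[testIds])
    prob <- c(prob, pr$probability)
  }
  report <- grab(evalReport(truth, prob, config$model$threshold))
  manifest <- list(seed = config$seed, nested = TRUE, timings = timings,
                   warnings = warnings)
  structure(list(manifest = manifest, cohort = cohort, report = report),
            class = "myoPipelineRun")
}

#' Human-readable pipeline summary
#'
#' Formats the REP sweep, the final feature subset with provenance, the
#' evaluation metrics (and comparison table when baselines ran) and any
#' warnings. Regenerating the report from a saved run reproduces it.
#'
#' @param run a `myoPipelineRun` from [runPipeline()].
#' @return character vector of report lines (invisibly printed with
#'   `cat`-style newlines via `print`).
#' @export
pipelineReport <- function(run) {
  m <- run$manifest
  lines <- c("== myoscreen pipeline report ==",
             sprintf("master seed: %d", m$seed))
  if (!is.null(run$imputation)) {
    lines <- c(lines, "", "-- imputation sweep (p, R2, r, REP) --",
               utils::capture.output(print(run$imputation$sweep,
                                           row.names = FALSE)),
               sprintf("chosen train proportion: %.2f (tolerance y = %.2f D)",
                       m$chosenP, m$tolerance))
  }
  if (!is.null(run$subset))
    lines <- c(lines, "", "-- final feature subset --",
               sprintf("  %s [%s]", subsetFactors(run$subset),
                       subsetProvenance(run$subset)))
  if (!is.null(run$report)) {
    met <- reportMetrics(run$report)
    lines <- c(lines, "", "-- evaluation --",
               sprintf("  %s: %.3f", names(met), met),
               sprintf("  auc: %.3f", run$report@auc))
    if (length(run$report@cvMean))
      lines <- c(lines, sprintf("  %d-fold cv accuracy: %.3f",
                                length(run$report@cvFolds),
                                run$report@cvMean))
  }
  if (!is.null(run$baselines))
    lines <- c(lines, "", "-- baseline comparison --",
               utils::capture.output(print(run$baselines,
                                           row.names = FALSE, digits = 3)))
  if (length(m$warnings))
    lines <- c(lines, "", "-- warnings --", paste0("  ", m$warnings))
  lines
}

#' @export
print.myoPipelineRun <- function(x, ...) {
  cat(pipelineReport(x), sep = "\n")
  invisible(x)
}
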