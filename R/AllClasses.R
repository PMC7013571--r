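#' MyopiaCohort: student-by-grade longitudinal cohort container
#'
#' A \linkS4class{SummarizedExperiment} specialised for longitudinal school
#' cohorts: rows are students, columns are grades (1..6 by default), and each
#' assay holds one measured factor as a student-by-grade numeric matrix.
#' Missing cells are `NA`. Factor metadata (kind and longitudinal transform
#' rule) lives in `metadata(x)$factorInfo`; static per-student attributes such
#' as gender live in `rowData`.
#'
#' Factor kinds follow the clinical grouping used throughout the package:
#' \describe{
#'   \item{objective}{time-invariant attributes (e.g. GENDER, number of
#'     myopic parents); transform rule `passthrough` (grade-1 value used).}
#'   \item{categorical_behavioral}{ordinal behaviour/diet frequencies;
#'     transform rule `sum` over grades 1-5.}
#'   \item{continuous_ocular}{continuous ocular/physiological measurements
#'     (axial length, keratometry, pulse, ...); transform rule `mean`.}
#'   \item{diopter}{refraction (RA) in diopters, negative = myopic;
#'     transform rule `annual_progress`.}
#' }
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @aliases MyopiaCohort-class
#' @exportClass MyopiaCohort
setClass("MyopiaCohort", contains = "SummarizedExperiment")

.validFactorKinds <- c("objective", "categorical_behavioral",
                       "continuous_ocular", "diopter")
.kindRule <- c(objective = "passthrough",
               categorical_behavioral = "sum",
               continuous_ocular = "mean",
               diopter = "annual_progress")

setValidity("MyopiaCohort", function(object) {
  msg <- character()
  fi <- metadata(object)$factorInfo
  if (is.null(fi))
    return("metadata(object)$factorInfo is missing")
  need <- c("name", "kind", "transform_rule")
  if (!all(need %in% names(fi)))
    msg <- c(msg, sprintf("factorInfo must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (!setequal(fi$name, assayNames(object)))
      msg <- c(msg, "factorInfo$name must match assayNames")
    bad <- !fi$kind %in% .validFactorKinds
    if (any(bad))
      msg <- c(msg, sprintf("unknown factor kind(s): %s",
                            paste(unique(fi$kind[bad]), collapse = ", ")))
    else {
      mism <- fi$transform_rule != unname(.kindRule[fi$kind])
      if (any(mism))
        msg <- c(msg, sprintf(
          "transform_rule inconsistent with kind for: %s",
          paste(fi$name[mism], collapse = ", ")))
    }
  }
  gr <- colData(object)$grade
  if (is.null(gr) || !is.numeric(gr) || any(gr != seq_along(gr) + gr[1] - 1))
    msg <- c(msg, "colData(object)$grade must be consecutive integers")
  if (length(msg)) msg else TRUE
})

#' Construct a MyopiaCohort from per-factor matrices
#'
#' @param factorValues named list of numeric matrices, one per factor, all of
#'   identical dimension (students x grades); `NA` marks missing cells.
#' @param factorInfo data.frame with columns `name`, `kind`,
#'   `transform_rule` (and optionally `description`) covering every factor.
#' @param grades integer vector of grade numbers (columns), default `1:6`.
#' @param studentIds character vector of student identifiers; defaults to the
#'   rownames of the first matrix.
#' @return a [MyopiaCohort-class] object.
#' @examples
#' ra <- matrix(0, 2, 6, dimnames = list(c("S1", "S2"), paste0("g", 1:6)))
#' fi <- data.frame(name = "RA", kind = "diopter",
#'                  transform_rule = "annual_progress")
#' MyopiaCohort(list(RA = ra), fi)
#' @export
MyopiaCohort <- function(factorValues, factorInfo, grades = NULL,
                         studentIds = NULL) {
  stopifnot(is.list(factorValues), length(factorValues) > 0,
            !is.null(names(factorValues)))
  dims <- vapply(factorValues, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all factor matrices must have identical dimensions")
  if (is.null(grades)) grades <- seq_len(dims[2, 1])
  if (is.null(studentIds)) studentIds <- rownames(factorValues[[1]])
  if (is.null(studentIds))
    studentIds <- sprintf("S%05d", seq_len(dims[1, 1]))
  factorValues <- lapply(factorValues, function(m) {
    dimnames(m) <- list(studentIds, paste0("g", grades))
    m
  })
  factorInfo <- as.data.frame(factorInfo)
  factorInfo <- factorInfo[match(names(factorValues), factorInfo$name), ,
                           drop = FALSE]
  if (anyNA(factorInfo$name))
    stop("factorInfo is missing entries for some factors")
  se <- SummarizedExperiment(
    assays = factorValues,
    rowData = DataFrame(row.names = studentIds),
    colData = DataFrame(grade = as.integer(grades),
                        row.names = paste0("g", grades)))
  metadata(se)$factorInfo <- factorInfo
  new("MyopiaCohort", se)
}

#' @describeIn MyopiaCohort factor metadata table (name, kind,
#'   transform_rule, ...).
#' @param x a `MyopiaCohort`.
#' @export
factorInfo <- function(x) metadata(x)$factorInfo

#' @describeIn MyopiaCohort names of the measured factors.
#' @export
factorNames <- function(x) assayNames(x)

#' @describeIn MyopiaCohort student identifiers.
#' @export
studentIds <- function(x) rownames(x)

#' @describeIn MyopiaCohort grade numbers spanned by the cohort.
#' @export
gradeLevels <- function(x) colData(x)$grade

#' @describeIn MyopiaCohort the student-by-grade matrix of one factor.
#' @param factor factor name.
#' @export
factorValues <- function(x, factor) {
  if (!factor %in% assayNames(x))
    stop(sprintf("unknown factor '%s'", factor))
  assay(x, factor)
}

setMethod("show", "MyopiaCohort", function(object) {
  fi <- factorInfo(object)
  nmiss <- sum(vapply(assays(object), function(a) sum(is.na(a)), numeric(1)))
  ncell <- nrow(object) * ncol(object) * length(assays(object))
  cat(sprintf("MyopiaCohort: %d students x grades %s, %d factors\n",
              nrow(object), paste(range(gradeLevels(object)), collapse = "-"),
              length(assayNames(object))))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s(%d)", names(table(fi$kind)), table(fi$kind)),
                    collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss, 100 * nmiss / ncell))
})

#' FeatureSubset: an ordered set of selected factors with provenance
#'
#' Produced by the screening stage. `provenance` records, per factor, whether
#' it entered via the univariate screen, the multivariate refit, or was
#' forced in by the analyst (RA is conventionally forced).
#'
#' @slot factors character vector of factor names, no duplicates.
#' @slot provenance character vector, same length, each one of
#'   `"univariate"`, `"multivariate"`, `"forced"`.
#' @exportClass FeatureSubset
setClass("FeatureSubset",
         representation(factors = "character", provenance = "character"))

setValidity("FeatureSubset", function(object) {
  if (anyDuplicated(object@factors)) return("duplicate factors")
  if (length(object@factors) != length(object@provenance))
    return("factors and provenance lengths differ")
  ok <- object@provenance %in% c("univariate", "multivariate", "forced")
  if (!all(ok)) return("invalid provenance value")
  TRUE
})

#' @describeIn FeatureSubset constructor.
#' @param factors,provenance see slots.
#' @export
FeatureSubset <- function(factors = character(),
                          provenance = rep("univariate", length(factors))) {
  new("FeatureSubset", factors = as.character(factors),
      provenance = as.character(provenance))
}

#' @describeIn FeatureSubset factor names in order.
#' @param x a `FeatureSubset`.
#' @export
subsetFactors <- function(x) x@factors

#' @describeIn FeatureSubset named provenance vector.
#' @export
subsetProvenance <- function(x) setNames(x@provenance, x@factors)

setMethod("show", "FeatureSubset", function(object) {
  cat(sprintf("FeatureSubset of %d factor(s)\n", length(object@factors)))
  if (length(object@factors))
    cat(paste0("  ", format(object@factors), "  [", object@provenance, "]",
               collapse = "\n"), "\n")
})

setMethod("length", "FeatureSubset", function(x) length(x@factors))

#' GbrtModel: a gradient-boosted regression tree ensemble
#'
#' Additive model \eqn{f_M(x) = f_0 + \nu \sum_m \sum_j c_{mj} I(x \in
#' R_{mj})}: a constant initial learner \eqn{f_0} (the training mean under
#' squared loss) plus `rounds` shallow regression trees fitted stage-wise to
#' pseudo-residuals, scaled by the shrinkage \eqn{\nu}.
#'
#' @slot f0 initial constant learner.
#' @slot shrinkage learning rate in (0, 1].
#' @slot trees list of regression trees (recursive node lists).
#' @slot featureNames training feature schema.
#' @slot rounds number of boosting rounds M.
#' @exportClass GbrtModel
setClass("GbrtModel",
         representation(f0 = "numeric", shrinkage = "numeric",
                        trees = "list", featureNames = "character",
                        rounds = "integer"))

setValidity("GbrtModel", function(object) {
  if (length(object@trees) != object@rounds)
    return("rounds must equal length(trees)")
  if (object@shrinkage <= 0 || object@shrinkage > 1)
    return("shrinkage must be in (0, 1]")
  TRUE
})

setMethod("show", "GbrtModel", function(object) {
  cat(sprintf(
    "GbrtModel: f0 = %.4g, %d tree(s), shrinkage %.3g, %d feature(s)\n",
    object@f0, object@rounds, object@shrinkage,
    length(object@featureNames)))
})

#' RepScore: the REP model-selection statistic
#'
#' Bundles the fitting goodness \eqn{R^2} (ratio of prediction spread to data
#' spread about the data mean), the absolute error rate \eqn{r} at tolerance
#' `tolerance`, and their ratio \eqn{REP = R^2 / r}. Larger REP is better;
#' a zero error rate yields `Inf`.
#'
#' @slot rSquared fitting goodness (nonnegative; may exceed 1 for
#'   over-dispersed predictions).
#' @slot errorRate proportion of predictions off by at least the tolerance.
#' @slot tolerance the tolerance y, in target units (diopters for RA).
#' @slot rep the ratio.
#' @exportClass RepScore
setClass("RepScore",
         representation(rSquared = "numeric", errorRate = "numeric",
                        tolerance = "numeric", rep = "numeric"))

setValidity("RepScore", function(object) {
  if (object@rSquared < 0) return("rSquared must be nonnegative")
  if (object@errorRate < 0 || object@errorRate > 1)
    return("errorRate must be in [0, 1]")
  if (object@errorRate > 0 &&
      !isTRUE(all.equal(object@rep, object@rSquared / object@errorRate)))
    return("rep must equal rSquared / errorRate")
  TRUE
})

setMethod("show", "RepScore", function(object) {
  cat(sprintf("RepScore: R2 = %.4g, r = %.4g (y = %.3g) => REP = %.4g\n",
              object@rSquared, object@errorRate, object@tolerance,
              object@rep))
})

#' FeatureMatrix: one normalized feature vector per student
#'
#' Output of the transform stage: students in rows, reduced factor features
#' in columns, min-max normalized to [0, 1] using statistics learned on the
#' training rows only (stored in `normParams` for round-tripping).
#'
#' @slot values numeric matrix (students x features), normalized.
#' @slot label binary outcome vector (1 = myopic at grade 6).
#' @slot normParams data.frame(feature, min, max) fitted on training rows.
#' @slot trainIds ids of the rows the normalization was fitted on.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
         representation(values = "matrix", label = "numeric",
                        normParams = "data.frame", trainIds = "character"))

setValidity("FeatureMatrix", function(object) {
  if (anyNA(object@values)) return("feature matrix contains missing values")
  if (length(object@label) != nrow(object@values))
    return("label length must match rows")
  TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf(
    "FeatureMatrix: %d students x %d features (prevalence %.3f)\n",
    nrow(object@values), ncol(object@values), mean(object@label)))
})

#' @describeIn FeatureMatrix the normalized matrix.
#' @param x a `FeatureMatrix`.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix the binary outcome vector.
#' @export
featureLabels <- function(x) x@label

#' @describeIn FeatureMatrix normalization parameters (per-feature min/max).
#' @export
normParams <- function(x) x@normParams

#' EvalReport: classification evaluation summary
#'
#' Confusion counts and the derived metrics (accuracy, precision,
#' sensitivity/recall, specificity, f1), trapezoidal AUC with the ROC
#' polyline, and stratified k-fold cross-validated accuracy.
#'
#' @slot counts named integer vector TP, FP, TN, FN.
#' @slot metrics named numeric vector of derived metrics.
#' @slot auc area under the ROC curve.
#' @slot rocPoints data.frame(fpr, tpr), monotone from (0,0) to (1,1).
#' @slot cvFolds per-fold accuracies.
#' @slot cvMean mean cross-validated accuracy.
#' @slot notes character vector of warnings (e.g. undefined denominators).
#' @exportClass EvalReport
setClass("EvalReport",
         representation(counts = "integer", metrics = "numeric",
                        auc = "numeric", rocPoints = "data.frame",
                        cvFolds = "numeric", cvMean = "numeric",
                        notes = "character"))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              object@counts["TP"], object@counts["FP"],
              object@counts["TN"], object@counts["FN"]))
  m <- object@metrics
  cat(sprintf(
    "  accuracy %.3f | precision %.3f | sensitivity %.3f | specificity %.3f | f1 %.3f\n",
    m["accuracy"], m["precision"], m["sensitivity"], m["specificity"],
    m["f1"]))
  if (length(object@auc)) cat(sprintf("  AUC %.3f\n", object@auc))
  if (length(object@cvMean))
    cat(sprintf("  %d-fold CV accuracy %.3f\n", length(object@cvFolds),
                object@cvMean))
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

#' @describeIn EvalReport named metric vector.
#' @param x an `EvalReport`.
#' @export
reportMetrics <- function(x) x@metrics

#' @describeIn EvalReport confusion counts.
#' @export
reportCounts <- function(x) x@counts

#' @describeIn EvalReport ROC polyline.
#' @export
rocPoints <- function(x) x@rocPoints
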