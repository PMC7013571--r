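#' Bundled published reference tables
#'
#' Small worked-example tables shipped with the package, used in tests and
#' in the acceptance script:
#' \describe{
#'   \item{univariate}{a published univariate screening result for 25
#'     candidate factors (correlation and p-value per factor).}
#'   \item{multivariate}{the matching multivariate regression table
#'     (coefficient, standard error, t, p).}
#'   \item{rep_sweep}{a published nine-row train-proportion sweep
#'     (p, R2, r) for REP-driven imputation-model selection.}
#'   \item{baseline_metrics}{published evaluation metrics for a linear SVM
#'     and five baseline classifiers.}
#' }
#'
#' @param name one of `"univariate"`, `"multivariate"`, `"rep_sweep"`,
#'   `"baseline_metrics"`.
#' @return a data.frame.
#' @examples
#' selectRepOptimal(referenceTable("rep_sweep"))$p  # 0.8
#' @export
referenceTable <- function(name = c("univariate", "multivariate",
                                    "rep_sweep", "baseline_metrics")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_reference.csv"),
                      package = "myoscreen", mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}
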