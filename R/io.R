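#' Read and write cohorts as CSV
#'
#' Long format has columns `student_id, grade, factor, value` (empty cell =
#' missing); wide format has one row per student and columns
#' `FACTOR_g1 ... FACTOR_g6`. Factor metadata travels in a separate CSV with
#' columns `name, kind, transform_rule` (and optionally `description`).
#'
#' @param cohort a [MyopiaCohort-class].
#' @param file path to the cohort CSV.
#' @param format `"long"` or `"wide"`.
#' @return `writeCohortCsv` returns `file` invisibly; `readCohortCsv`
#'   returns a [MyopiaCohort-class].
#' @export
writeCohortCsv <- function(cohort, file, format = c("long", "wide")) {
  format <- match.arg(format)
  gl <- gradeLevels(cohort)
  if (format == "long") {
    parts <- lapply(factorNames(cohort), function(nm) {
      m <- assay(cohort, nm)
      data.table::data.table(
        student_id = rep(rownames(m), ncol(m)),
        grade = rep(gl, each = nrow(m)),
        factor = nm, value = as.vector(m))
    })
    dt <- data.table::rbindlist(parts)
    data.table::setorder(dt, student_id, grade, factor)
  } else {
    cols <- lapply(factorNames(cohort), function(nm) {
      m <- assay(cohort, nm)
      colnames(m) <- paste0(nm, "_g", gl)
      m
    })
    dt <- data.table::as.data.table(do.call(cbind, cols))
    dt <- cbind(data.table::data.table(student_id = studentIds(cohort)), dt)
  }
  data.table::fwrite(dt, file, na = "")
  invisible(file)
}

#' @rdname writeCohortCsv
#' @param factorInfoFile path to the factor metadata CSV; when `NULL` on
#'   read, kinds are inferred from factor names via [defaultFactorSet()].
#' @export
readCohortCsv <- function(file, factorInfoFile = NULL,
                          format = c("long", "wide")) {
  format <- match.arg(format)
  dt <- data.table::fread(file, na.strings = "")
  if (format == "long") {
    ids <- sort(unique(dt$student_id))
    grades <- sort(unique(dt$grade))
    facs <- unique(dt$factor)
    vals <- lapply(facs, function(nm) {
      sub <- dt[dt$factor == nm, ]
      m <- matrix(NA_real_, length(ids), length(grades),
                  dimnames = list(ids, paste0("g", grades)))
      m[cbind(match(sub$student_id, ids), match(sub$grade, grades))] <-
        sub$value
      m
    })
    names(vals) <- facs
  } else {
    ids <- dt$student_id
    meas <- setdiff(names(dt), "student_id")
    facs <- unique(sub("_g[0-9]+$", "", meas))
    grades <- sort(unique(as.integer(sub("^.*_g", "", meas))))
    vals <- lapply(facs, function(nm) {
      m <- as.matrix(dt[, paste0(nm, "_g", grades), with = FALSE])
      dimnames(m) <- list(ids, paste0("g", grades))
      m
    })
    names(vals) <- facs
  }
  fi <- if (!is.null(factorInfoFile)) read.csv(factorInfoFile)
        else {
          def <- defaultFactorSet()
          def[def$name %in% facs, c("name", "description", "kind",
                                    "transform_rule")]
        }
  MyopiaCohort(vals, fi, grades = grades, studentIds = as.character(ids))
}

#' @rdname writeCohortCsv
#' @export
writeFactorInfo <- function(cohort, file) {
  write.csv(factorInfo(cohort), file, row.names = FALSE)
  invisible(file)
}
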