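# Shared fixtures: tiny cohorts built in code, plus the bundled published
# reference tables.

refUni <- referenceTable("univariate")
refMulti <- referenceTable("multivariate")
refSweep <- referenceTable("rep_sweep")
refBase <- referenceTable("baseline_metrics")

# a tiny hand-built cohort: 3 students, 6 grades, RA + one factor per kind
tinyCohort <- function() {
  ids <- c("S1", "S2", "S3")
  ra <- rbind(c(0, -0.5, -1.0, -1.5, -2.0, -2.5),
              c(1, 1, 1, 1, 1, 1),
              c(0.5, 0.25, 0.0, -0.25, -0.5, -0.75))
  cola <- rbind(c(2, 0, 3, 1, 1, 2),
                c(0, 0, 0, 0, 0, 0),
                c(1, 1, 1, 1, 1, 1))
  al <- rbind(c(22, 22.5, 23, 23.5, 24, 24.5),
              c(23, 23, 23, 23, 23, 23),
              c(24, 24, 24, 24, 24, 24))
  gender <- rbind(rep(1, 6), rep(0, 6), rep(1, 6))
  rownames(ra) <- rownames(cola) <- rownames(al) <- rownames(gender) <- ids
  fi <- data.frame(
    name = c("GENDER", "COLA", "AL", "RA"),
    kind = c("objective", "categorical_behavioral", "continuous_ocular",
             "diopter"),
    transform_rule = c("passthrough", "sum", "mean", "annual_progress"))
  MyopiaCohort(list(GENDER = gender, COLA = cola, AL = al, RA = ra), fi)
}

smallConfig <- function(n = 300, seed = 1, ...)
  cohortConfig(nStudents = n, seed = seed, ...)

# factor panel with all effects removed (null cohort)
nullFactorSet <- function() {
  fs <- defaultFactorSet()
  fs$effect <- 0
  fs
}

# independent oracle: brute-force best single regression stump by
# enumerating every (feature, midpoint cut) pair
bruteStump <- function(X, y, minLeaf = 1) {
  best <- list(sse = Inf)
  for (j in seq_len(ncol(X))) {
    cuts <- sort(unique(X[, j]))
    if (length(cuts) < 2) next
    mids <- (head(cuts, -1) + cuts[-1]) / 2
    for (cut in mids) {
      l <- X[, j] <= cut
      if (sum(l) < minLeaf || sum(!l) < minLeaf) next
      pred <- ifelse(l, mean(y[l]), mean(y[!l]))
      sse <- sum((y - pred)^2)
      if (sse < best$sse - 1e-12)
        best <- list(sse = sse, pred = pred)
    }
  }
  if (is.infinite(best$sse)) best$pred <- rep(mean(y), length(y))
  best
}
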