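test_that("fitting goodness follows the spread-ratio definition", {
  expect_equal(fittingGoodness(c(1, 5, 3, 2), c(1, 5, 3, 2)), 1)
  expect_equal(fittingGoodness(c(1, 5, 3, 2), rep(2.75, 4)), 0)
  # hand example: actual (1,2,3), predicted (1,3,5), xbar = 2
  # numerator (1-2)^2+(3-2)^2+(5-2)^2 = 11, denominator 2
  expect_warning(r2 <- fittingGoodness(c(1, 2, 3), c(1, 3, 5)),
                 "exceeds 1")
  expect_equal(r2, 11 / 2)
  expect_error(fittingGoodness(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(fittingGoodness(1, 1), "at least 2")
})

test_that("absolute error rate counts strict misses only", {
  a <- c(0, 0, 0)
  expect_equal(absoluteErrorRate(a, a, 0.5), 0)
  expect_equal(absoluteErrorRate(a, a + 1, 0.5), 1)
  # errors 0.1, 0.5, 0.9 at y = 0.5: the boundary error 0.5 is a miss
  expect_equal(absoluteErrorRate(a, a + c(0.1, 0.5, 0.9), 0.5), 2 / 3)
  expect_error(absoluteErrorRate(numeric(), numeric(), 0.5), "empty")
  expect_error(absoluteErrorRate(a, a, 0), "positive")
})

test_that("REP is the ratio, with Inf for perfect error rates", {
  s <- repScore(0.789, 0.145)
  expect_equal(s@rep, 0.789 / 0.145)
  expect_equal(round(s@rep, 3), 5.441)
  expect_equal(repScore(0, 0.3)@rep, 0)
  expect_equal(repScore(0.7, 1)@rep, 0.7)
  expect_identical(repScore(0.5, 0)@rep, Inf)
  expect_error(repScore(-0.1, 0.5), "nonnegative")
})

test_that("REP maximization picks p = 0.8 on the published sweep", {
  sel <- selectRepOptimal(refSweep)
  expect_equal(sel$p, 0.8)
  expect_equal(sel$sweep$REP, sel$sweep$R2 / sel$sweep$r, tolerance = 1e-12)
  # ties break toward more training data
  tie <- data.frame(p = c(0.3, 0.6), R2 = c(0.5, 0.5), r = c(0.1, 0.1))
  expect_equal(selectRepOptimal(tie)$p, 0.6)
  expect_equal(selectRepOptimal(data.frame(p = 0.4, R2 = 1, r = 0.2))$p,
               0.4)
})

test_that("the sweep from a real selection run is self-consistent", {
  cc <- smallConfig(n = 500, seed = 21)
  coh <- applyMissingness(simulateCohort(cc), cc)
  imp <- selectImputationModel(coh, c("AL", "COLA", "GENDER"),
                               pGrid = c(0.4, 0.6, 0.8), rounds = 20,
                               seed = 3)
  expect_equal(imp$sweep$REP, imp$sweep$R2 / imp$sweep$r, tolerance = 1e-12)
  best <- imp$sweep[which.max(imp$sweep$REP), ]
  expect_equal(imp$p, best$p)
  # single-element grid is chosen trivially
  imp1 <- selectImputationModel(coh, c("AL", "COLA"), pGrid = 0.7,
                                rounds = 10, seed = 3)
  expect_equal(imp1$p, 0.7)
})

test_that("fillMissing fills exactly the missing RA cells, deterministically", {
  cc <- smallConfig(n = 400, seed = 22)
  full <- simulateCohort(cc)
  coh <- applyMissingness(full, cc)
  facs <- c("AL", "COLA", "GENDER")
  imp <- selectImputationModel(coh, facs, pGrid = 0.8, rounds = 30,
                               seed = 4)
  f1 <- fillMissing(coh, imp$model, facs)
  f2 <- fillMissing(coh, imp$model, facs)
  ra <- SummarizedExperiment::assay(f1, "RA")
  raIn <- SummarizedExperiment::assay(coh, "RA")
  expect_false(anyNA(ra))
  expect_identical(SummarizedExperiment::assay(f2, "RA"), ra)
  # observed cells untouched, filled cells flagged
  flag <- S4Vectors::metadata(f1)$imputedRA
  expect_identical(ra[!flag], raIn[!flag])
  expect_identical(unname(flag), unname(is.na(raIn)))
  # a cohort with nothing missing is returned unchanged
  f0 <- fillMissing(full, imp$model, facs)
  expect_identical(SummarizedExperiment::assay(f0, "RA"),
                   SummarizedExperiment::assay(full, "RA"))
})

test_that("GBRT imputation beats mean imputation on held-back truth", {
  cc <- cohortConfig(nStudents = 800, seed = 23)
  full <- simulateCohort(cc)
  masked <- applyMissingness(full, cc)
  facs <- subsetFactors(selectFinal(refMulti))
  imp <- selectImputationModel(masked, facs, pGrid = c(0.6, 0.8),
                               rounds = 60, seed = 5)
  filled <- fillMissing(masked, imp$model, facs)
  raTrue <- SummarizedExperiment::assay(full, "RA")
  raFill <- SummarizedExperiment::assay(filled, "RA")
  raMask <- SummarizedExperiment::assay(masked, "RA")
  hidden <- is.na(raMask)
  # mean-imputation baseline: per-grade mean of the observed cells
  gmeans <- colMeans(raMask, na.rm = TRUE)
  raMean <- raMask
  for (g in seq_along(gmeans)) raMean[hidden[, g], g] <- gmeans[g]
  rGbrt <- absoluteErrorRate(raTrue[hidden], raFill[hidden], 0.5)
  rMean <- absoluteErrorRate(raTrue[hidden], raMean[hidden], 0.5)
  expect_lt(rGbrt, rMean)
})
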