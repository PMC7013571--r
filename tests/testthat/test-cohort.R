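test_that("invalid configurations are rejected naming the field", {
  expect_error(cohortConfig(nStudents = 0), "nStudents")
  expect_error(cohortConfig(maleFraction = 1.2), "maleFraction")
  expect_error(cohortConfig(noiseSd = -1), "noiseSd")
  expect_error(cohortConfig(missingRateMean = 0.5, missingRateMax = 0.2),
               "missingRateMean")
  expect_error(cohortConfig(effectSizes = c(NOPE = 1)), "effectSizes")
})

test_that("simulation is deterministic and matches the configured sex ratio", {
  cc <- smallConfig(n = 3112, seed = 1)
  coh1 <- simulateCohort(cc)
  coh2 <- simulateCohort(cc)
  expect_identical(SummarizedExperiment::assays(coh1),
                   SummarizedExperiment::assays(coh2))
  male <- mean(SummarizedExperiment::assay(coh1, "GENDER")[, 1])
  se <- sqrt(0.578 * (1 - 0.578) / 3112)
  expect_lt(abs(male - 0.578), 2 * se)
  # complete table
  expect_false(anyNA(SummarizedExperiment::assay(coh1, "RA")))
})

test_that("zero effects and zero noise give pure constant drift", {
  cc <- smallConfig(n = 40, seed = 2, factorSet = nullFactorSet(),
                    noiseSd = 0)
  coh <- simulateCohort(cc)
  ra <- SummarizedExperiment::assay(coh, "RA")
  for (g in 2:6)
    expect_equal(ra[, g], ra[, 1] + (g - 1) * cc$driftPerYear,
                 tolerance = 1e-12)
})

test_that("a planted risk effect shows up with its sign in the raw table", {
  fs <- nullFactorSet()
  fs$effect[fs$name == "COLA"] <- 0.4
  cc <- smallConfig(n = 2000, seed = 3, factorSet = fs)
  coh <- simulateCohort(cc)
  colaSum <- rowSums(SummarizedExperiment::assay(coh, "COLA")[, 1:5])
  ra <- SummarizedExperiment::assay(coh, "RA")
  progression <- -(ra[, 5] - ra[, 1]) / 4  # myopic progression, + = worse
  r <- cor(colaSum, progression)
  expect_gt(r, 0.1)
})

test_that("missingness honours the grade schedule and the seed", {
  cc <- cohortConfig(nStudents = 3112, seed = 4)
  coh <- simulateCohort(cc)
  m1 <- applyMissingness(coh, cc)
  m2 <- applyMissingness(coh, cc)
  expect_identical(SummarizedExperiment::assays(m1),
                   SummarizedExperiment::assays(m2))
  ra <- SummarizedExperiment::assay(m1, "RA")
  expect_false(anyNA(ra[, 1]))                       # grade 1 complete
  p6 <- mean(is.na(ra[, 6]))
  se <- sqrt(0.4 * 0.6 / 3112)
  expect_lt(abs(p6 - 0.40), 3 * se)                  # grade-6 RA ~ max rate
  # mean per-factor missing rate ~ configured mean for a non-RA factor
  al <- SummarizedExperiment::assay(m1, "AL")
  expect_lt(abs(mean(is.na(al)) - 0.15), 3 * sqrt(0.15 * 0.85 / (3112 * 6)))
  # zero rates are the identity
  cc0 <- cohortConfig(nStudents = 50, seed = 5, missingRateMean = 0,
                      missingRateMax = 0)
  coh0 <- simulateCohort(cc0)
  expect_identical(SummarizedExperiment::assays(applyMissingness(coh0, cc0)),
                   SummarizedExperiment::assays(coh0))
})

test_that("myopia labels use an inclusive -0.5 D cutoff", {
  coh <- tinyCohort()  # grade-6 RA: -2.5, 1, -0.75
  expect_identical(unname(deriveMyopiaLabel(coh)), c(1L, 0L, 1L))
  # boundary: exactly at the threshold counts as myopic
  ra <- SummarizedExperiment::assay(coh, "RA")
  ra["S2", 6] <- -0.5
  SummarizedExperiment::assay(coh, "RA") <- ra
  expect_identical(unname(deriveMyopiaLabel(coh)), c(1L, 1L, 1L))
  expect_identical(unname(deriveMyopiaLabel(coh, threshold = -1)),
                   c(1L, 0L, 0L))
  ra["S2", 6] <- NA
  SummarizedExperiment::assay(coh, "RA") <- ra
  expect_error(deriveMyopiaLabel(coh), "S2")
})

test_that("cohorts round-trip through long and wide CSV", {
  cc <- smallConfig(n = 20, seed = 6)
  coh <- applyMissingness(simulateCohort(cc), cc)
  for (fmt in c("long", "wide")) {
    f <- tempfile(fileext = ".csv")
    writeCohortCsv(coh, f, format = fmt)
    back <- readCohortCsv(f, format = fmt)
    for (nm in factorNames(coh))
      expect_equal(SummarizedExperiment::assay(back, nm),
                   SummarizedExperiment::assay(coh, nm),
                   tolerance = 1e-12, ignore_attr = FALSE)
    unlink(f)
  }
})
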