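test_that("univariate screen handles perfect, null and degenerate factors", {
  y <- c(1.2, -0.5, 3.1, 0.4, -2.2, 0.9, 1.5, -1.1)
  X <- cbind(same = y, flat = rep(2, 8))
  res <- univariateScreen(X, y)
  expect_equal(res$correlation[res$factor == "same"], 1)
  expect_equal(res$p_value[res$factor == "same"], 0)
  expect_equal(res$correlation[res$factor == "flat"], 0)
  expect_equal(res$p_value[res$factor == "flat"], 1)
  expect_error(univariateScreen(X[1:2, ], y[1:2]), "at least 3")
  expect_error(univariateScreen(X, rep(1, 8)), "constant")
})

test_that("t-based p agrees with the exhaustive permutation oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 2, 3, 4, 6)
  robs <- cor(x, y)
  perms <- matrix(unlist(combinat_perms <- {
    # all 120 orderings of y, generated recursively
    permute <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        out <- c(out, lapply(permute(v[-i]), function(p) c(v[i], p)))
      out
    }
    permute(y)
  }), nrow = 5)
  rperm <- apply(perms, 2, function(p) cor(x, p))
  pPerm <- mean(abs(rperm) >= abs(robs) - 1e-12)
  pT <- univariateScreen(matrix(x, dimnames = list(NULL, "x")), y)$p_value
  expect_lt(abs(pT - pPerm), 0.02)
})

test_that("preliminary selection is strict and order-preserving", {
  res <- data.frame(factor = c("a", "b", "c"),
                    correlation = c(0.3, 0.2, 0.1),
                    p_value = c(0.049, 0.05, 0.051))
  sel <- selectPreliminary(res, alpha = 0.05)
  expect_identical(subsetFactors(sel), "a")  # strict inequality
  expect_warning(empty <- selectPreliminary(res, alpha = 0.0001),
                 "no factor")
  expect_length(empty, 0)
  expect_identical(subsetFactors(selectPreliminary(res, alpha = 0.9)),
                   c("a", "b", "c"))
  # all 25 published univariate rows survive at 0.05
  expect_length(selectPreliminary(refUni, 0.05), 25)
  # top-k variant ranks by p
  expect_identical(subsetFactors(selectPreliminary(res, topK = 2)),
                   c("a", "b"))
})

test_that("enlarging alpha never shrinks the selected set", {
  set.seed(42)
  res <- data.frame(factor = paste0("f", 1:40),
                    correlation = runif(40, -1, 1),
                    p_value = runif(40))
  prev <- character()
  for (a in c(0.01, 0.05, 0.1, 0.3, 0.6, 0.95)) {
    cur <- subsetFactors(suppressWarnings(selectPreliminary(res, a)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("multivariate fit matches the normal-equations oracle", {
  set.seed(7)
  n <- 10
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 3] + rnorm(n, sd = 0.3)
  res <- multivariateFit(X, colnames(X), y)
  # explicit (X'X)^-1 X'y with intercept
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(res$coefficient, beta[-1, 1], tolerance = 1e-9,
               ignore_attr = TRUE)
  sigma2 <- sum((y - Xd %*% beta)^2) / (n - ncol(Xd))
  se <- sqrt(diag(solve(t(Xd) %*% Xd)) * sigma2)[-1]
  expect_equal(res$std_err, se, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(res$t_stat, res$coefficient / res$std_err, tolerance = 1e-12)
})

test_that("simple regression p equals the univariate p; exact recovery", {
  set.seed(8)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  X <- matrix(x, dimnames = list(NULL, "x"))
  expect_equal(multivariateFit(X, "x", y)$p_value,
               univariateScreen(X, y)$p_value, tolerance = 1e-9)
  # exact linear target, no noise
  X2 <- cbind(x1 = rnorm(12), x2 = rnorm(12))
  y2 <- 2 * X2[, 1] - 3 * X2[, 2]
  res <- suppressWarnings(multivariateFit(X2, colnames(X2), y2))
  expect_equal(res$coefficient, c(2, -3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(res$p_value), 1e-12)
})

test_that("collinear columns are dropped with a warning naming them", {
  set.seed(9)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x, c = rnorm(20))
  y <- x + rnorm(20)
  expect_warning(res <- multivariateFit(X, colnames(X), y), "b")
  expect_identical(res$factor, c("a", "c"))
})

test_that("final selection forces RA in without duplicating it", {
  res <- data.frame(factor = c("AL", "RA", "K1"),
                    p_value = c(0.01, 0.02, 0.5))
  sel <- selectFinal(res, alpha = 0.05, forced = "RA")
  expect_identical(subsetFactors(sel), c("AL", "RA"))
  expect_identical(unname(subsetProvenance(sel)["RA"]), "multivariate")
  # forced-only when nothing survives
  sel0 <- selectFinal(data.frame(factor = character(),
                                 p_value = numeric()),
                      alpha = 0.05, forced = "RA")
  expect_identical(subsetFactors(sel0), "RA")
  expect_identical(unname(subsetProvenance(sel0)), "forced")
})

test_that("the published multivariate table yields the 15-factor panel", {
  sel <- selectFinal(refMulti, alpha = 0.05, forced = "RA")
  expect_setequal(subsetFactors(sel),
                  c("DAI", "GENDER", "JTR", "YTR", "JG", "YW", "AL", "K1",
                    "K2", "PULSE", "COLA", "REDM", "WHIM", "EGG", "RA"))
  expect_length(sel, 15)
})
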