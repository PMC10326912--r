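test_that("fitOls recovers exact lines and handles degenerate variance", {
  x <- 1:10
  y <- 2 + 3 * x
  f <- fitOls(y, cbind(x = x))
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(f$r.squared, 1)
  ## constant response orthogonal to a centered covariate
  f0 <- fitOls(rep(5, 10), cbind(x = x - mean(x)))
  expect_equal(unname(f0$coefficients[2L]), 0, tolerance = 1e-12)
  expect_equal(f0$r.squared, 0)
  expect_error(fitOls(1:3, cbind(a = 1:3, b = 4:6)),
               "rank-deficient|n > p")
  expect_error(fitOls(1:4, matrix(rnorm(12), 4, 3)), "n > p")
})

test_that("fitOls equals the normal-equations oracle on random data", {
  set.seed(42)
  n <- 50
  X <- matrix(rnorm(n * 3, 10, 4), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 1.5 - 0.7 * X[, 1] + 0.2 * X[, 3] + rnorm(n)
  f <- fitOls(y, X)
  Xd <- cbind(1, X)
  betaOracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1L]
  expect_equal(unname(f$coefficients), unname(betaOracle), tolerance = 1e-10)
  resid <- y - Xd %*% betaOracle
  s2 <- sum(resid^2) / (n - 4)
  seOracle <- sqrt(diag(solve(t(Xd) %*% Xd)) * s2)
  expect_equal(unname(f$se), unname(seOracle), tolerance = 1e-10)
  sm <- summary(stats::lm(y ~ X))
  expect_equal(f$r.squared, sm$r.squared, tolerance = 1e-12)
  expect_equal(f$sigma, sm$sigma, tolerance = 1e-12)
  expect_equal(unname(f$fstatistic), unname(sm$fstatistic[1L]),
               tolerance = 1e-10)
  ## standardized coefficients: beta * sd(x) / sd(y)
  expect_equal(unname(f$std.coefficients),
               unname(f$coefficients[-1L] * apply(X, 2, sd) / sd(y)),
               tolerance = 1e-12)
})

test_that("partial F p-values obey the t^2 = F identity and degeneracy rules", {
  set.seed(7)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  xc <- rnorm(n)
  y <- 3 + X %*% c(1, -2) + 0.5 * xc + rnorm(n)
  p <- partialFPValue(y, X, xc, "add")
  fit <- stats::lm(y ~ X + xc)
  tval <- summary(fit)$coefficients["xc", "t value"]
  expect_equal(attr(p, "F"), tval^2, tolerance = 1e-10)
  expect_equal(as.numeric(p),
               summary(fit)$coefficients["xc", "Pr(>|t|)"], tolerance = 1e-10)
  ## removal p of a column equals its own t-test p in the full model
  pr <- partialFPValue(y, cbind(X, xc = xc), X[, "a"], "remove")
  expect_equal(as.numeric(pr),
               summary(fit)$coefficients[2L, "Pr(>|t|)"], tolerance = 1e-10)
  ## perfect predictor on noiseless data is decisive
  yln <- 1 + 2 * xc
  pPerf <- partialFPValue(yln, matrix(nrow = n, ncol = 0), xc, "add")
  expect_lt(as.numeric(pPerf), 1e-12)
  ## duplicate of an included column: degenerate, treated as non-significant
  pDup <- partialFPValue(y, X, X[, "a"], "add")
  expect_equal(as.numeric(pDup), 1)
  expect_true(attr(pDup, "degenerate"))
})

test_that("stepwise selection finds the generating covariate and validates thresholds", {
  set.seed(11)
  n <- 128
  X <- matrix(rnorm(n * 10, 50, 8), n, 10)
  colnames(X) <- as.character(seq(60, 150, by = 10))
  ## vanishing noise: the generating covariate is selected exactly (any
  ## residual noise would let other candidates enter at the nominal rate,
  ## since t statistics are scale-free)
  y <- 2 + 3 * X[, "100"]
  m <- cbind(`55` = y, X)
  sel <- stepwiseSelect(55, m)
  expect_s4_class(sel, "IonModel")
  expect_identical(sel@covariateMz, 100L)
  expect_equal(unname(sel@fit$coefficients), c(2, 3), tolerance = 1e-8)
  expect_identical(sel@trace$action[1L], "enter")
  ## with small noise the generating covariate is always among the selected
  yn <- y + rnorm(n, sd = 0.01)
  mn <- cbind(`55` = yn, X)
  seln <- stepwiseSelect(55, mn)
  expect_true(100L %in% seln@covariateMz)
  expect_equal(unname(seln@fit$coefficients[c("(Intercept)", "100")]),
               c(2, 3), tolerance = 1e-2)
  expect_error(stepwiseSelect(55, m, pEnter = 0.10, pRemove = 0.05),
               "pEnter must be <")
  ## zero-variance dependent -> skip record
  m2 <- m; m2[, "55"] <- 42
  sk <- stepwiseSelect(55, m2)
  expect_s3_class(sk, "ionModelSkip")
  expect_match(sk$reason, "zero-variance")
})

test_that("stepwise agrees with the exhaustive add1/drop1 oracle", {
  for (seed in 1:25) {
    m <- randomStepwiseInstance(seed)
    sel <- stepwiseSelect(90, m)
    expect_identical(sort(sel@covariateMz), stepwiseOracle(90, m),
                     label = sprintf("seed %d", seed))
  }
})

test_that("stepwise is invariant to row and candidate-column order", {
  m <- randomStepwiseInstance(101)
  base <- stepwiseSelect(90, m)
  set.seed(1)
  mRow <- m[sample(nrow(m)), ]
  mCol <- m[, c("80", "90", "50", "70", "60")]
  expect_identical(sort(stepwiseSelect(90, mRow)@covariateMz),
                   sort(base@covariateMz))
  expect_identical(sort(stepwiseSelect(90, mCol)@covariateMz),
                   sort(base@covariateMz))
  expect_equal(stepwiseSelect(90, mRow)@fit$coefficients,
               base@fit$coefficients, tolerance = 1e-10)
})

test_that("pure-noise candidates enter at about the nominal rate", {
  hits <- 0L
  for (seed in 1:500) {
    set.seed(seed + 7000)
    y <- rnorm(30)
    x <- rnorm(30)
    m <- cbind(`10` = y, `20` = x)
    sel <- stepwiseSelect(10, m, pEnter = 0.05, pRemove = 0.10)
    if (length(sel@covariateMz)) hits <- hits + 1L
  }
  ## Binomial(500, 0.05): mean 25, sd 4.87; allow ~4 sd
  expect_gte(hits, 7L)
  expect_lte(hits, 45L)
})

test_that("training produces one model per non-degenerate panel ion", {
  gen <- makeLinearTruthLibrary(makeDefaultTruth(seed = 5), n = 128, seed = 5)
  tab <- trainCoefficientTable(gen$library, nIons = 20)
  expect_s4_class(tab, "CoefficientTable")
  expect_length(panelMz(tab), 20L)
  expect_identical(length(tab@models) + length(tab@skips), 20L)
  ## the pinned base ion is exactly constant after normalization -> skipped
  expect_identical(names(tab@skips), "82")
  for (m in ionModels(tab)) {
    expect_false(m@dependentMz %in% m@covariateMz)
    expect_true(all(m@covariateMz %in% panelMz(tab)))
    expect_gte(m@fit$r.squared, 0.85)
  }
  expect_error(trainCoefficientTable(
    newSpectrumLibrary(gen$library@spectra[1:10]), nIons = 20),
    "more than nIons")
})

test_that("noiseless linear truth yields perfect single-covariate models", {
  truth <- makeDefaultTruth(seed = 2, noiseSD = 1)
  noiseless <- new("LinearTruth", mz = truth@mz, mean = truth@mean,
                   loading = truth@loading, loading2 = truth@loading2,
                   noiseSD = numeric(length(truth@mz)))
  gen <- makeLinearTruthLibrary(noiseless, n = 60, seed = 9)
  tab <- trainCoefficientTable(gen$library, nIons = 20)
  for (m in ionModels(tab)) {
    expect_equal(m@fit$r.squared, 1, tolerance = 1e-9)
    expect_lt(max(abs(m@fit$residuals)), 1e-7)
    ## collinearity guard caps the model at one exact covariate
    expect_identical(length(m@covariateMz), 1L)
  }
})

test_that("predictIon applies coefficients, zero-fills, and passes through means", {
  fit <- list(coefficients = c(`(Intercept)` = 10, `198` = 0.5),
              se = c(1, 0.1), df = 10L, sigma = 1, r.squared = 0.9,
              fstatistic = 10, f.pvalue = 0.01,
              std.coefficients = c(`198` = 0.8), n = 12,
              mean.y = 40, mean.x = c(`198` = 60))
  m <- new("IonModel", dependentMz = 182L, covariateMz = 198L, fit = fit,
           trace = data.frame())
  q <- normalizeToBasePeak(newSpectrum(c(82, 198), c(100, 60), id = "q"))
  expect_equal(predictIon(m, q), 40)
  qMissing <- normalizeToBasePeak(newSpectrum(82, 100, id = "q2"))
  expect_warning(pv <- predictIon(m, qMissing), "198")
  expect_equal(pv, 10)
  expect_error(predictIon(m, newSpectrum(82, 50, id = "raw")), "normalized")
  ## OLS passes through the mean point: mean covariates -> mean response
  gen <- makeLinearTruthLibrary(makeDefaultTruth(seed = 6), n = 60, seed = 6)
  tab <- trainCoefficientTable(gen$library, nIons = 20)
  mm <- ionModels(tab)[[3L]]
  meanQ <- new("Spectrum", id = "mean", label = "unlabeled", source = "",
               peaks = c(mm@fit$mean.x, `82` = 100), normalized = TRUE)
  expect_equal(predictIon(mm, meanQ), mm@fit$mean.y, tolerance = 1e-8)
})

test_that("predictAll returns one row per model with exact residual identity", {
  gen <- makeLinearTruthLibrary(makeDefaultTruth(seed = 8), n = 80, seed = 8)
  tab <- trainCoefficientTable(gen$library, nIons = 20)
  q <- gen$library[[1L]]
  pr <- predictAll(tab, q)
  expect_identical(nrow(pr), length(tab@models))
  expect_equal(pr$residual, pr$measured - pr$predicted)
  sig <- vapply(tab@models[as.character(pr$mz)], function(m) m@fit$sigma,
                numeric(1))
  expect_equal(pr$std.residual, pr$residual / unname(sig))
  ## training residuals average to zero per model
  res <- residualMatrix(tab, gen$library)
  expect_lt(max(abs(colMeans(res))), 1e-8)
})

test_that("coefficient tables survive JSON round trips and export CSV", {
  gen <- makeLinearTruthLibrary(makeDefaultTruth(seed = 12), n = 60, seed = 12)
  tab <- trainCoefficientTable(gen$library, nIons = 20)
  path <- tempfile(fileext = ".json")
  writeCoefficientTable(tab, path)
  back <- readCoefficientTable(path)
  expect_identical(panelMz(back), panelMz(tab))
  expect_identical(names(back@models), names(tab@models))
  expect_identical(back@skips, tab@skips)
  q <- gen$library[[5L]]
  expect_equal(predictAll(back, q), predictAll(tab, q), tolerance = 1e-12)
  csv <- tempfile(fileext = ".csv")
  writeCoefficientCSV(tab, csv)
  flat <- utils::read.csv(csv, check.names = FALSE)
  expect_identical(nrow(flat), 20L)
  expect_true(all(as.character(panelMz(tab)) %in% names(flat)))
  ## unselected covariates stay empty
  m1 <- tab@models[[1L]]
  row1 <- flat[flat$dependent.mz == m1@dependentMz, ]
  unsel <- setdiff(panelMz(tab), c(m1@dependentMz, m1@covariateMz))
  expect_true(all(is.na(row1[, as.character(unsel)])))
})

test_that("predictions are invariant to raw-intensity rescaling of the query", {
  gen <- makeLinearTruthLibrary(makeDefaultTruth(seed = 13), n = 60, seed = 13)
  tab <- trainCoefficientTable(gen$library, nIons = 20)
  raw <- newSpectrum(c(82, 182, 94), c(1000, 700, 300), id = "q")
  raw10 <- newSpectrum(c(82, 182, 94), c(10000, 7000, 3000), id = "q")
  p1 <- suppressWarnings(predictAll(tab, normalizeToBasePeak(raw)))
  p2 <- suppressWarnings(predictAll(tab, normalizeToBasePeak(raw10)))
  expect_equal(p1, p2, tolerance = 1e-12)
})
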