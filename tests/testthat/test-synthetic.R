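test_that("default network is deterministic, in-range and well-formed", {
  n1 <- makeDefaultNetwork(0)
  n2 <- makeDefaultNetwork(0)
  expect_identical(n1, n2)
  p1 <- tempfile(); p2 <- tempfile()
  writeNetworkConfig(n1, p1); writeNetworkConfig(n2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(makeDefaultNetwork(1), n1))
  expect_true(validObject(n1))
  expect_true(all(n1@E0 >= 1.6 & n1@E0 <= 3.0))
  expect_identical(n1@atoms[[n1@precursor]], 70L)
  ## loose channel: highest E0 and largest v among first-generation channels
  fg <- which(n1@parent == n1@precursor)
  expect_gte(length(fg), 3L)
  loose <- fg[which.max(n1@E0[fg])]
  expect_identical(which.max(n1@v[fg]), which(fg == loose))
  expect_gte(log10(max(n1@v[fg]) / min(n1@v[fg])), 3)
  ## at least one sequential channel and a valid topological order
  expect_gte(sum(n1@parent != n1@precursor), 1L)
  expect_false(is.null(easiMS:::.topo_order(n1@species, n1@parent, n1@product)))
})

test_that("replicate simulation is seed-deterministic and invariant-clean", {
  net <- makeDefaultNetwork(0)
  prof <- defaultLabProfile(1, n = 12)
  lib1 <- simulateReplicateLibrary(net, prof)
  lib2 <- simulateReplicateLibrary(net, prof)
  expect_length(lib1@spectra, 12L)
  for (i in seq_len(12))
    expect_identical(peaks(lib1[[i]]), peaks(lib2[[i]]))
  p1 <- tempfile(); p2 <- tempfile()
  writeMSP(lib1, p1); writeMSP(lib2, p2)
  expect_identical(readLines(p1), readLines(p2))
  ## different seed -> different spectra
  lib3 <- simulateReplicateLibrary(net, defaultLabProfile(1, seed = 99, n = 12))
  expect_false(identical(peaks(lib1[[1]]), peaks(lib3[[1]])))
  ## every spectrum satisfies the normalized-spectrum invariants
  for (i in seq_len(12)) {
    s <- lib1[[i]]
    expect_true(validObject(s))
    expect_equal(max(peaks(s)), 100)
    expect_true(all(peaks(s) >= 0 & peaks(s) <= 100))
    expect_false("303" %in% names(peaks(s)))  # precursor dropped by default
  }
})

test_that("degenerate profiles produce identical spectra; cold profiles error", {
  net <- makeDefaultNetwork(0)
  frozen <- labProfile(60, 1e-12, log(1e-6), 1e-12, noiseCV = 0, n = 5,
                       seed = 4, name = "frozen")
  lib <- simulateReplicateLibrary(net, frozen)
  for (i in 2:5)
    expect_equal(peaks(lib[[i]]), peaks(lib[[1]]), tolerance = 1e-6)
  cold <- labProfile(1.2, 0.05, log(1e-6), 0.1, noiseCV = 0, n = 5,
                     seed = 4, name = "cold")
  expect_error(simulateReplicateLibrary(net, cold), "energy mean")
})

test_that("within-lab replicate spectra carry strong fragment correlations", {
  net <- makeDefaultNetwork(0)
  lib <- simulateReplicateLibrary(net, defaultLabProfile(1))
  mat <- buildAbundanceMatrix(lib, selectTopIons(lib, n = 4))
  cm <- pearsonCorrelationMap(mat)
  expect_gte(max(abs(cm$r)), 0.9)
})

test_that("linear truth library has the advertised linear structure", {
  truth <- makeDefaultTruth(seed = 0)
  expect_true(validObject(truth))
  expect_identical(length(truth@mz), 20L)
  gen <- makeLinearTruthLibrary(truth, n = 128, seed = 1)
  expect_length(gen$library@spectra, 128L)
  expect_lt(gen$clipFraction, 0.01)
  mat <- buildAbundanceMatrix(gen$library,
                              new("IonPanel", mz = truth@mz,
                                  score = rev(seq_along(truth@mz)) * 1.0))
  ## regression of each loaded ion on the latent factor: R^2 near the
  ## signal fraction 0.95 when averaged over seeds (a single seed's latent
  ## variance can sit a couple of sigma off 1 at n = 128)
  loaded <- as.character(truth@mz[truth@loading != 0])
  panel <- new("IonPanel", mz = truth@mz,
               score = rev(seq_along(truth@mz)) * 1.0)
  meanR2 <- mean(vapply(1:5, function(s) {
    g <- makeLinearTruthLibrary(truth, n = 128, seed = s)
    m <- buildAbundanceMatrix(g$library, panel)
    f <- g$factors[, "f"]
    mean(vapply(loaded, function(k)
      summary(stats::lm(m[, k] ~ f))$r.squared, numeric(1)))
  }, numeric(1)))
  expect_equal(meanR2, 0.95, tolerance = 0.03)
  ## zero loadings -> mutually uncorrelated columns up to sampling error
  null <- new("LinearTruth", mz = c(50L, 60L, 70L, 82L),
              mean = c(40, 50, 60, 100), loading = numeric(4),
              loading2 = numeric(4), noiseSD = c(2, 2, 2, 0))
  genN <- makeLinearTruthLibrary(null, n = 200, seed = 2)
  matN <- buildAbundanceMatrix(genN$library,
                               new("IonPanel", mz = null@mz,
                                   score = c(4, 3, 2, 1)))
  cmN <- pearsonCorrelationMap(matN[, c("50", "60", "70")])
  expect_lt(max(abs(cmN$r)), 0.25)
  ## noiseless: every pairwise ion regression is exact
  noiseless <- new("LinearTruth", mz = truth@mz, mean = truth@mean,
                   loading = truth@loading, loading2 = truth@loading2,
                   noiseSD = numeric(20))
  genP <- makeLinearTruthLibrary(noiseless, n = 50, seed = 3)
  matP <- buildAbundanceMatrix(genP$library,
                               new("IonPanel", mz = truth@mz,
                                   score = rev(seq_along(truth@mz)) * 1.0))
  loaded <- as.character(truth@mz[truth@loading != 0])
  r2p <- stats::cor(matP[, loaded[1]], matP[, loaded[2]])^2
  expect_equal(r2p, 1, tolerance = 1e-10)
  expect_error(makeLinearTruthLibrary(truth, n = 10, seed = 1), "n > k")
})

test_that("excess clipping is an error, not a silent distortion", {
  hot <- new("LinearTruth", mz = c(50L, 82L), mean = c(99, 100),
             loading = c(0, 0), loading2 = c(0, 0), noiseSD = c(8, 0))
  expect_error(makeLinearTruthLibrary(hot, n = 100, seed = 1), "clip")
})

test_that("trueCoefficients reproduces the population regression", {
  truth <- makeDefaultTruth(seed = 0)
  i <- which(truth@loading != 0)[1:2]
  yMz <- truth@mz[i[1]]; xMz <- truth@mz[i[2]]
  b <- trueCoefficients(truth, yMz, xMz)
  ly <- truth@loading[i[1]]; lx <- truth@loading[i[2]]
  slope <- ly * lx / (lx^2 + truth@noiseSD[i[2]]^2)
  expect_equal(unname(b[as.character(xMz)]), slope, tolerance = 1e-12)
  expect_equal(unname(b["(Intercept)"]),
               truth@mean[i[1]] - slope * truth@mean[i[2]], tolerance = 1e-12)
  ## empirical check: OLS on a large sample approaches the implied truth
  gen <- makeLinearTruthLibrary(truth, n = 128, seed = 44)
  mat <- buildAbundanceMatrix(gen$library,
                              new("IonPanel", mz = truth@mz,
                                  score = rev(seq_along(truth@mz)) * 1.0))
  fit <- fitOls(mat[, as.character(yMz)], mat[, as.character(xMz), drop = FALSE])
  expect_lt(abs(fit$coefficients[2L] - slope), 3 * fit$se[2L])
  expect_error(trueCoefficients(truth, 9999, xMz), "not in the truth panel")
})

test_that("two-lab shift pushes measurements outside the training range", {
  ex <- suppressWarnings(twoLabExperiment())
  trainMat <- buildAbundanceMatrix(ex$train, ex$table@panel)
  testMat <- buildAbundanceMatrix(ex$test, ex$table@panel)
  outside <- vapply(colnames(trainMat), function(k)
    mean(testMat[, k] < min(trainMat[, k]) | testMat[, k] > max(trainMat[, k])),
    numeric(1))
  ## at least one modeled ion has most measurements beyond the training range
  expect_gte(max(outside), 0.5)
  ## and the linear models still beat the centroid baseline there
  varying <- ex$perIon[ex$perIon$trainSD > 1e-6, ]
  expect_true(all(varying$rmsModel < varying$rmsCentroid))
})
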