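## Synthetic-data generators: a default kinetic fragmentation network, a
## replicate-library simulator driven by latent (energy, time) draws, and a
## linear-truth generator with known coefficients for parameter-recovery
## testing. The defaults here ARE the study conditions the rest of the
## package is validated under; see the methods vignette for their rationale.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default fragmentation network
#'
#' A 70-atom hypothetical precursor ABCD+ with three competitive
#' first-generation channels whose critical energies span 1.6-3.0 eV and
#' whose frequency factors span three orders of magnitude — the loosest
#' channel (largest v) having the highest E0 — plus two sequential sibling
#' channels from AB+ (AB+ -> A+ and AB+ -> B+) whose critical energies sit
#' close together, so their branching ratio varies slowly and the A+/B+
#' abundance pair is nearly proportional — the consecutive-fragment
#' near-collinearity replicate spectra are known for. The seed jitters the
#' energies slightly while preserving the qualitative structure; the same
#' seed always returns the identical network.
#'
#' @param seed integer RNG seed (default 0).
#' @return a [FragmentationNetwork-class].
#' @export
makeDefaultNetwork <- function(seed = 0) {
  .withSeed(seed, {
    u <- stats::runif(5, -1, 1)
    pw <- data.frame(
      parent  = c("ABCD+", "ABCD+", "ABCD+", "AB+", "AB+"),
      product = c("AB+",   "BC+",   "C+",    "A+",  "B+"),
      ## tight, low-E0 rearrangement -> loose, high-E0 direct cleavage
      E0      = c(1.6 + 0.1 * (u[1] + 1) / 2,          # in [1.60, 1.70]
                  2.2 + 0.1 * u[2],                    # in [2.10, 2.30]
                  3.0 - 0.1 * (u[3] + 1) / 2,          # in [2.90, 3.00]
                  2.55 + 0.05 * u[4],                  # sibling pair:
                  2.65 + 0.05 * u[5]),                 #   gap <= 0.2 eV
      log10v  = c(9, 10.5, 12, 6.8, 6.5),
      stringsAsFactors = FALSE)
    newFragmentationNetwork(
      precursor = "ABCD+", pathways = pw,
      atoms = c("ABCD+" = 70L, "AB+" = 40L, "BC+" = 44L, "C+" = 18L,
                "A+" = 22L, "B+" = 20L),
      mass = c("ABCD+" = 303L, "AB+" = 182L, "BC+" = 198L, "C+" = 82L,
               "A+" = 105L, "B+" = 94L))
  })
}

#' Construct a LabProfile
#'
#' @param energyMean,energySpread mean and SD of the internal-energy draw (eV).
#' @param logTimeMean,logTimeSpread mean and SD of log observation time
#'   (time in seconds).
#' @param noiseCV coefficient of variation of the per-ion multiplicative
#'   log-normal measurement noise.
#' @param n number of replicate spectra.
#' @param seed RNG seed.
#' @param name laboratory tag.
#' @return a [LabProfile-class].
#' @export
labProfile <- function(energyMean, energySpread, logTimeMean, logTimeSpread,
                       noiseCV = 0.03, n = 128, seed = 1, name = "Lab") {
  new("LabProfile", energyMean = energyMean, energySpread = energySpread,
      logTimeMean = logTimeMean, logTimeSpread = logTimeSpread,
      noiseCV = noiseCV, n = as.integer(n), seed = as.integer(seed),
      name = name)
}

#' Default laboratory profiles for the two-lab experiment
#'
#' Lab 1 is the training laboratory: internal energy 60 +/- 3 eV
#' (SD = 5% of the mean, so a +/-15% window at 3 SD), observation time
#' log-normal around 1 microsecond (log-SD 0.1), 3% multiplicative
#' measurement noise, 128 replicates. Lab 2 is the extrapolation target:
#' energy mean increased by 33% and time mean by 50% (same spreads),
#' 120 replicates — conditions under which measured abundances fall partly
#' outside Lab 1's training range.
#'
#' @param lab 1 (training) or 2 (shifted validation).
#' @param seed RNG seed (default: the lab number).
#' @param n override the number of spectra.
#' @param noiseCV override the measurement-noise CV.
#' @return a [LabProfile-class].
#' @export
defaultLabProfile <- function(lab = 1, seed = lab, n = NULL, noiseCV = 0.03) {
  stopifnot(lab %in% c(1, 2))
  if (lab == 1)
    labProfile(energyMean = 60, energySpread = 3,
               logTimeMean = log(1e-6), logTimeSpread = 0.1,
               noiseCV = noiseCV, n = if (is.null(n)) 128 else n,
               seed = seed, name = "Lab 1")
  else
    labProfile(energyMean = 60 * 4 / 3, energySpread = 3,
               logTimeMean = log(1.5e-6), logTimeSpread = 0.1,
               noiseCV = noiseCV, n = if (is.null(n)) 120 else n,
               seed = seed, name = "Lab 2")
}

#' Simulate a replicate spectral library from kinetics
#'
#' For each replicate, draws an internal energy and an observation time from
#' the lab profile, computes the species fractions of the network at that
#' (E, t), renders them as a nominal-mass spectrum (species masses from the
#' network), applies independent multiplicative log-normal measurement noise
#' per ion, and normalizes to the base peak. Identical (network, profile)
#' inputs give identical libraries.
#'
#' @param network a [FragmentationNetwork-class].
#' @param lab a [LabProfile-class].
#' @param dropPrecursor drop the surviving precursor ion from spectra
#'   (default TRUE: only fragments are recorded).
#' @param inheritExcess see [speciesFractions()].
#' @return a [SpectrumLibrary-class] of `lab@n` normalized spectra labeled
#'   known-positive, sources tagged with the lab name.
#' @export
simulateReplicateLibrary <- function(network, lab, dropPrecursor = TRUE,
                                     inheritExcess = FALSE) {
  stopifnot(is(network, "FragmentationNetwork"), is(lab, "LabProfile"))
  firstGen <- network@E0[network@parent == network@precursor]
  if (lab@energyMean - 3 * lab@energySpread < min(firstGen))
    stop("profile energy mean - 3 SD falls below every first-generation E0: ",
         "all-fragment signal would vanish; raise the energy mean")
  sdlog <- sqrt(log(1 + lab@noiseCV^2))
  .withSeed(lab@seed, {
    E <- stats::rnorm(lab@n, lab@energyMean, lab@energySpread)
    tt <- exp(stats::rnorm(lab@n, lab@logTimeMean, lab@logTimeSpread))
    spectra <- vector("list", lab@n)
    for (i in seq_len(lab@n)) {
      fr <- speciesFractions(network, max(E[i], 0), tt[i],
                             inheritExcess = inheritExcess)
      if (dropPrecursor) fr <- fr[setdiff(names(fr), network@precursor)]
      if (lab@noiseCV > 0)
        fr <- fr * exp(stats::rnorm(length(fr), -sdlog^2 / 2, sdlog))
      keep <- fr > 0
      s <- newSpectrum(mz = network@mass[names(fr)[keep]],
                       abundance = fr[keep],
                       id = sprintf("%s_%04d", gsub("\\s+", "", lab@name), i),
                       label = "known-positive", source = lab@name)
      spectra[[i]] <- normalizeToBasePeak(s)
    }
    newSpectrumLibrary(spectra, compound = "synthetic-ABCD")
  })
}

#' Default linear-truth generating model
#'
#' A one-factor linear model over a 20-ion panel: the base ion (m/z 82) is
#' pinned at abundance 100 with zero loading and zero noise, and the other
#' 19 ions get seeded mean abundances in [25, 80] and latent-factor loadings
#' of magnitude `noiseSD * sqrt(sf / (1 - sf))` with seeded signs, so that
#' each loaded ion's variance is the fraction `sf` signal and `1 - sf`
#' noise.
#'
#' @param k panel size (default 20).
#' @param signalFraction per-ion signal variance fraction
#'   `loading^2 / (loading^2 + noiseSD^2)` (default 0.95).
#' @param noiseSD measurement-noise SD in abundance units (default 1).
#' @param seed RNG seed (default 0).
#' @return a [LinearTruth-class].
#' @export
makeDefaultTruth <- function(k = 20, signalFraction = 0.95, noiseSD = 1,
                             seed = 0) {
  stopifnot(k >= 3, signalFraction > 0, signalFraction < 1)
  mzPool <- c(82L, 182L, 83L, 94L, 42L, 198L, 77L, 96L, 105L, 183L, 303L,
              272L, 55L, 152L, 51L, 68L, 122L, 97L, 81L, 93L)
  if (k > length(mzPool))
    mzPool <- c(mzPool, setdiff(seq(40L, 400L), mzPool))
  mz <- mzPool[seq_len(k)]
  amp <- noiseSD * sqrt(signalFraction / (1 - signalFraction))
  .withSeed(seed, {
    means <- c(100, stats::runif(k - 1, 25, 80))
    signs <- c(0, sample(c(-1, 1), k - 1, replace = TRUE))
    new("LinearTruth", mz = mz, mean = means,
        loading = signs * amp,
        loading2 = numeric(k),
        noiseSD = c(0, rep(noiseSD, k - 1)))
  })
}

#' Generate a spectral library with known linear structure
#'
#' Draws `abundance(i, j) = mean_j + loading_j * f_i + loading2_j * g_i +
#' noise_ij` with `f_i`, `g_i` standard-normal latent factors and
#' independent Gaussian noise, clips to [0.1, 100] (counting clip events;
#' more than 5% clipped is an error because clipping breaks the linear
#' structure the generator exists to provide), renders spectra and
#' normalizes to the base peak.
#'
#' @param truth a [LinearTruth-class].
#' @param n number of spectra (must exceed the panel size + 2).
#' @param seed RNG seed.
#' @return list: `library` (a normalized [SpectrumLibrary-class]), `truth`,
#'   `factors` (the latent draws, n x 2), `clipFraction`.
#' @export
makeLinearTruthLibrary <- function(truth, n, seed = 1) {
  stopifnot(is(truth, "LinearTruth"))
  k <- length(truth@mz)
  if (n <= k + 2L) stop("need n > k + 2 spectra (k = ", k, ")")
  .withSeed(seed, {
    f <- stats::rnorm(n)
    g <- stats::rnorm(n)
    eps <- matrix(stats::rnorm(n * k), n, k) %*% diag(truth@noiseSD, k)
    ab <- matrix(truth@mean, n, k, byrow = TRUE) +
      outer(f, truth@loading) + outer(g, truth@loading2) + eps
    clipped <- sum(ab < 0.1 | ab > 100)
    clipFraction <- clipped / length(ab)
    if (clipFraction > 0.05)
      stop(sprintf(paste0("%.1f%% of generated abundances needed clipping ",
                          "(> 5%%); reduce loadings/noise or recenter means"),
                   100 * clipFraction))
    ab <- pmin(pmax(ab, 0.1), 100)
    spectra <- lapply(seq_len(n), function(i) {
      normalizeToBasePeak(newSpectrum(
        mz = truth@mz, abundance = ab[i, ],
        id = sprintf("truth_%04d", i), label = "known-positive",
        source = "linear-truth"))
    })
    list(library = newSpectrumLibrary(spectra, compound = "linear-truth"),
         truth = truth,
         factors = cbind(f = f, g = g),
         clipFraction = clipFraction)
  })
}

#' Population regression coefficients implied by a LinearTruth
#'
#' For a dependent ion and a covariate set, computes the exact coefficients
#' of the population least-squares regression under the generating model
#' (covariance `Sigma = L L' + L2 L2' + diag(noiseSD^2)`). These are the
#' "true" values fitted coefficients should recover.
#'
#' @param truth a [LinearTruth-class].
#' @param dependentMz the dependent ion.
#' @param covariateMz integer vector of covariate ions.
#' @return named numeric vector: `(Intercept)` then one coefficient per
#'   covariate m/z.
#' @export
trueCoefficients <- function(truth, dependentMz, covariateMz) {
  stopifnot(is(truth, "LinearTruth"))
  idx <- match(c(dependentMz, covariateMz), truth@mz)
  if (anyNA(idx)) stop("ion(s) not in the truth panel")
  L <- cbind(truth@loading, truth@loading2)
  Sigma <- L %*% t(L) + diag(truth@noiseSD^2, length(truth@mz))
  yi <- idx[1L]; xi <- idx[-1L]
  if (!length(xi))
    return(stats::setNames(truth@mean[yi], "(Intercept)"))
  beta <- solve(Sigma[xi, xi, drop = FALSE], Sigma[xi, yi])
  b0 <- truth@mean[yi] - sum(beta * truth@mean[xi])
  stats::setNames(c(b0, beta), c("(Intercept)", as.character(covariateMz)))
}

#' Two-laboratory extrapolation experiment
#'
#' Trains a coefficient table on a Lab-1 replicate library simulated from
#' the kinetic network and evaluates, per modeled panel ion, the RMS
#' prediction residual on Lab-2 spectra (shifted energy/time conditions)
#' for both the linear models and the centroid baseline. The phenomenon
#' under test: Lab-2 abundances fall partly outside the Lab-1 training
#' range, so the consensus spectrum mispredicts them, while the linear
#' models extrapolate along the kinetic trend.
#'
#' @param network a [FragmentationNetwork-class]
#'   (default [makeDefaultNetwork()]).
#' @param lab1,lab2 [LabProfile-class] objects
#'   (defaults [defaultLabProfile()]).
#' @param pEnter,pRemove stepwise thresholds.
#' @return list: `table` (the trained [CoefficientTable-class]),
#'   `perIon` (data.frame: mz, rmsModel, rmsCentroid, ratio, trainSD),
#'   `train`, `test` (the simulated libraries).
#' @export
twoLabExperiment <- function(network = makeDefaultNetwork(),
                             lab1 = defaultLabProfile(1),
                             lab2 = defaultLabProfile(2),
                             pEnter = 0.05, pRemove = 0.10) {
  train <- simulateReplicateLibrary(network, lab1)
  test <- simulateReplicateLibrary(network, lab2)
  nIons <- ncol(.fullAbundanceMatrix(train))
  table <- trainCoefficientTable(train, nIons = nIons,
                                 pEnter = pEnter, pRemove = pRemove)
  resModel <- residualMatrix(table, test)
  trainMat <- buildAbundanceMatrix(train, table@panel)
  cent <- colMeans(trainMat)
  testMat <- buildAbundanceMatrix(test, table@panel)
  keys <- colnames(resModel)
  resCent <- sweep(testMat[, keys, drop = FALSE], 2, cent[keys])
  perIon <- data.frame(
    mz = as.integer(keys),
    rmsModel = sqrt(colMeans(resModel^2)),
    rmsCentroid = sqrt(colMeans(resCent^2)),
    trainSD = apply(trainMat[, keys, drop = FALSE], 2, stats::sd))
  perIon$ratio <- perIon$rmsModel / perIon$rmsCentroid
  rownames(perIon) <- NULL
  list(table = table, perIon = perIon, train = train, test = test)
}
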