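## Shared fixtures, all built in code at test time.

## small MSP text written to a temp file
writeTempMSP <- function(text) {
  path <- tempfile(fileext = ".msp")
  writeLines(text, path)
  path
}

## three-spectrum toy library with known ranking structure:
## mean abundances  A(82) = 90, B(182) = 50, C(198) = 10
toyLibrary <- function() {
  mk <- function(id, ab) {
    normalizeToBasePeak(newSpectrum(c(82, 182, 198), ab, id = id))
  }
  newSpectrumLibrary(list(
    mk("s1", c(1000, 500, 100)),
    mk("s2", c(900, 450, 90)),
    mk("s3", c(800, 400, 80))), compound = "toy")
}

## simple two-level chain:  M+ -> AB+ -> B+   (plus a competitive channel)
chainNetwork <- function() {
  pw <- data.frame(
    parent  = c("M+", "M+", "AB+"),
    product = c("AB+", "C+", "B+"),
    E0 = c(1.8, 2.6, 2.2), log10v = c(9, 11, 8))
  newFragmentationNetwork("M+", pw,
    atoms = c("M+" = 30L, "AB+" = 18L, "C+" = 12L, "B+" = 9L),
    mass = c("M+" = 200L, "AB+" = 120L, "C+" = 80L, "B+" = 60L))
}

## seeded random cascade network with <= maxSpecies species, plus an
## (E, t) pair chosen so the root's total decay is neither trivial nor
## numerically extinct
randomNetwork <- function(seed, maxSpecies = 6) {
  set.seed(seed)
  nSp <- sample(3:maxSpecies, 1)
  species <- paste0("S", seq_len(nSp))
  parent <- character(nSp - 1L)
  product <- character(nSp - 1L)
  for (i in 2:nSp) {       # random cascade: each species hangs off an earlier one
    parent[i - 1L] <- species[sample(i - 1L, 1)]
    product[i - 1L] <- species[i]
  }
  pw <- data.frame(parent = parent, product = product,
                   E0 = runif(nSp - 1L, 1, 3),
                   log10v = runif(nSp - 1L, 6, 10))
  net <- newFragmentationNetwork(
    species[1L], pw,
    atoms = stats::setNames(c(20L, sample(5:15, nSp - 1L, replace = TRUE)),
                            species))
  E <- runif(1, 12, 40)
  rates <- easiMS:::.edgeRates(net, E)
  kRoot <- sum(rates[parent == species[1L]])
  t <- if (kRoot > 0) runif(1, 0.05, 5) / kRoot else 1e-6
  list(network = net, E = E, t = t)
}

## abundance matrix (n x 5) for a stepwise instance with known structure:
## dependent "90" driven by a random subset of candidates 50/60/70/80
randomStepwiseInstance <- function(seed, n = 60) {
  set.seed(seed)
  X <- matrix(rnorm(n * 4, mean = 50, sd = 10), n, 4)
  ## mildly correlate candidates so selection is not orthogonal-trivial
  X[, 2] <- X[, 2] + 0.5 * X[, 1]
  X[, 4] <- X[, 4] - 0.3 * X[, 3]
  nSig <- sample(0:3, 1)
  sig <- sample(4, nSig)
  beta <- runif(4, -0.6, 0.6)
  beta[setdiff(seq_len(4), sig)] <- 0
  y <- 20 + X %*% beta + rnorm(n, sd = sample(c(1, 4, 10), 1))
  m <- cbind(y, X)
  colnames(m) <- c("90", "50", "60", "70", "80")
  m
}

## independent mixed-stepwise oracle built on stats::add1 / stats::drop1,
## following the same protocol and tie-breaks as stepwiseSelect: enter the
## smallest partial-F p <= pEnter (tie -> lower m/z), then sweep removals
## of the largest p >= pRemove (tie -> lower m/z), until stable.
stepwiseOracle <- function(yMz, matrix, pEnter = 0.05, pRemove = 0.10) {
  cols <- colnames(matrix)
  dat <- as.data.frame(matrix)
  names(dat) <- paste0("m", cols)
  yv <- paste0("m", yMz)
  cand <- setdiff(names(dat), yv)
  candMz <- as.integer(sub("^m", "", cand))
  included <- character(0)
  for (iter in 1:100) {
    changed <- FALSE
    fml <- stats::reformulate(if (length(included)) included else "1",
                              response = yv)
    fit <- stats::lm(fml, data = dat)
    pool <- setdiff(cand, included)
    if (length(pool)) {
      scope <- stats::as.formula(paste("~ . +", paste(pool, collapse = " + ")))
      a1 <- stats::add1(fit, scope = scope, test = "F")
      ps <- a1[pool, "Pr(>F)"]
      ord <- order(ps, candMz[match(pool, cand)], na.last = TRUE)
      best <- ord[1L]
      if (!is.na(ps[best]) && ps[best] <= pEnter) {
        included <- c(included, pool[best])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(included)) break
      fml <- stats::reformulate(included, response = yv)
      fit <- stats::lm(fml, data = dat)
      d1 <- stats::drop1(fit, test = "F")
      ps <- d1[included, "Pr(>F)"]
      ord <- order(-ps, candMz[match(included, cand)])
      worst <- ord[1L]
      if (!is.na(ps[worst]) && ps[worst] >= pRemove) {
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sort(as.integer(sub("^m", "", included)))
}
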