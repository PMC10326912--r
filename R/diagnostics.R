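#' Bivariate Pearson correlation map of panel ions
#'
#' All unordered pairs of matrix columns, with Pearson r and the two-sided
#' p-value from the exact t transform `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. Columns with zero variance are excluded from
#' testing and reported in the `dropped` attribute. For a k-ion panel the
#' map has `choose(k, 2)` pairs.
#'
#' @param matrix numeric matrix (spectra x ions or spectra x models),
#'   columns named.
#' @return data.frame with columns `col1`, `col2`, `r`, `p`, `n`;
#'   attribute `dropped` lists excluded zero-variance columns.
#' @export
pearsonCorrelationMap <- function(matrix) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (n < 3L) stop("need at least 3 rows to test correlations")
  if (is.null(colnames(matrix)))
    colnames(matrix) <- as.character(seq_len(ncol(matrix)))
  vars <- apply(matrix, 2, stats::var)
  dropped <- colnames(matrix)[vars == 0]
  keep <- matrix[, vars > 0, drop = FALSE]
  k <- ncol(keep)
  if (k < 2L) {
    out <- data.frame(col1 = character(0), col2 = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0))
    attr(out, "dropped") <- dropped
    return(out)
  }
  R <- stats::cor(keep)
  idx <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[idx]
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))
  out <- data.frame(col1 = colnames(keep)[idx[, 1L]],
                    col2 = colnames(keep)[idx[, 2L]],
                    r = r, p = p, n = n, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Exact finite-sample standard errors of skewness and kurtosis
#'
#' `SE_skew = sqrt(6n(n-1) / ((n-2)(n+1)(n+3)))` and
#' `SE_kurt = sqrt(24n(n-1)^2 / ((n-3)(n-2)(n+3)(n+5)))`, the standard
#' errors that accompany the bias-corrected sample skewness and excess
#' kurtosis. Both shrink toward 0 as n grows; at n = 128 the kurtosis SE is
#' 0.425.
#'
#' @param n sample size (>= 4).
#' @return list with elements `skew` and `kurtosis`.
#' @export
momentStandardErrors <- function(n) {
  if (n < 4) stop("moment standard errors require n >= 4")
  n <- as.numeric(n)
  seSkew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  seKurt <- sqrt(24 * n * (n - 1)^2 / ((n - 3) * (n - 2) * (n + 3) * (n + 5)))
  list(skew = seSkew, kurtosis = seKurt)
}

#' Residual moment diagnostics
#'
#' Bias-corrected sample skewness and excess kurtosis of a residual vector,
#' with significance flags against their exact finite-sample standard
#' errors. A moment is flagged when its magnitude exceeds
#' `multiplier * SE` (default multiplier 2; set 1 to read the SE itself as
#' the margin of error). Positive significant excess kurtosis indicates
#' leptokurtic residuals (wider tails than Gaussian).
#'
#' @param residuals numeric vector, n >= 4, non-constant.
#' @param multiplier significance multiple of the SE (default 2).
#' @return list: `skewness`, `se.skew`, `skew.significant`,
#'   `excess.kurtosis`, `se.kurtosis`, `kurtosis.significant`, `n`.
#' @export
residualMoments <- function(residuals, multiplier = 2) {
  n <- length(residuals)
  if (n < 4L) stop("need at least 4 residuals")
  if (stats::var(residuals) == 0) stop("residuals have zero variance")
  se <- momentStandardErrors(n)
  sk <- e1071::skewness(residuals, type = 2)   # bias-corrected (SPSS-style)
  ku <- e1071::kurtosis(residuals, type = 2)   # bias-corrected excess kurtosis
  list(skewness = sk, se.skew = se$skew,
       skew.significant = abs(sk) > multiplier * se$skew,
       excess.kurtosis = ku, se.kurtosis = se$kurtosis,
       kurtosis.significant = abs(ku) > multiplier * se$kurtosis,
       n = n)
}

#' P-P plot coordinates for standardized residuals
#'
#' Sorts the residuals and pairs the standard-normal cumulative probability
#' of each value (theoretical axis) with the plotting-position empirical
#' cumulative probability `(i - 0.5) / n`. Points near the identity line
#' indicate approximately normal residuals.
#'
#' @param standardizedResiduals numeric vector, n >= 2.
#' @return data.frame with columns `theoretical` and `empirical`, both in
#'   (0, 1), sorted in nondecreasing order.
#' @export
ppCoordinates <- function(standardizedResiduals) {
  n <- length(standardizedResiduals)
  if (n < 2L) stop("need at least 2 residuals")
  z <- sort(standardizedResiduals)
  data.frame(theoretical = stats::pnorm(z),
             empirical = (seq_len(n) - 0.5) / n)
}

#' Residual cross-correlation map
#'
#' Pearson correlation map over per-model residual columns, plus the
#' fraction of pairs significant at level `alpha`. After successful
#' modeling the residuals should be largely decorrelated: the fraction
#' should sit near `alpha` (the false-positive rate), unlike the heavily
#' correlated input abundances.
#'
#' @param residualMatrix numeric matrix, spectra x models.
#' @param alpha significance level (default 0.05).
#' @return list: `map` (the correlation data.frame), `fractionSignificant`,
#'   `nPairs`, `alpha`.
#' @export
residualCrossCorrelation <- function(residualMatrix, alpha = 0.05) {
  map <- pearsonCorrelationMap(residualMatrix)
  nPairs <- nrow(map)
  frac <- if (nPairs) mean(map$p < alpha) else NA_real_
  list(map = map, fractionSignificant = frac, nPairs = nPairs, alpha = alpha)
}

#' Centroid-baseline residuals
#'
#' The naive comparator: predict every panel ion by its training-set mean
#' (centroid / consensus) abundance and report the query's residuals against
#' it. The linear models must beat this baseline to justify their use.
#'
#' @param library normalized training [SpectrumLibrary-class].
#' @param panel an [IonPanel-class].
#' @param query a normalized [Spectrum-class].
#' @return data.frame with columns `mz`, `measured`, `centroid`, `residual`
#'   (measured minus centroid).
#' @export
centroidBaseline <- function(library, panel, query) {
  stopifnot(is(query, "Spectrum"))
  if (!isTRUE(query@normalized)) stop("query spectrum must be normalized")
  mat <- buildAbundanceMatrix(library, panel)
  cent <- colMeans(mat)
  keys <- as.character(panel@mz)
  meas <- vapply(keys, function(k)
    if (k %in% names(query@peaks)) query@peaks[[k]] else 0, numeric(1))
  data.frame(mz = panel@mz, measured = unname(meas),
             centroid = unname(cent[keys]),
             residual = unname(meas - cent[keys]))
}

#' Residual matrix of a coefficient table over a library
#'
#' Applies [predictAll()] to every spectrum and assembles the spectra x
#' models matrix of raw residuals (measured minus predicted).
#'
#' @param table a [CoefficientTable-class].
#' @param library a normalized [SpectrumLibrary-class].
#' @return numeric matrix, rownames = spectrum ids, colnames = dependent m/z.
#' @export
residualMatrix <- function(table, library) {
  stopifnot(is(table, "CoefficientTable"), is(library, "SpectrumLibrary"))
  mzs <- vapply(table@models, function(m) m@dependentMz, integer(1))
  out <- matrix(NA_real_, nrow = length(library), ncol = length(mzs),
                dimnames = list(spectrumIds(library), as.character(mzs)))
  for (i in seq_len(length(library))) {
    pr <- predictAll(table, library[[i]])
    out[i, as.character(pr$mz)] <- pr$residual
  }
  out
}

#' Full residual validity report
#'
#' The statistical-validity assessment of a trained coefficient table over a
#' (training or validation) library: per-model residual moments with exact
#' SEs and significance flags, P-P coordinates of the standardized
#' residuals, and the residual cross-correlation map with its
#' fraction-significant summary.
#'
#' @param table a [CoefficientTable-class].
#' @param library a normalized [SpectrumLibrary-class].
#' @param alpha significance level for residual pair correlations.
#' @param multiplier moment-significance multiple of the SE (see
#'   [residualMoments()]).
#' @return list of class `ResidualReport`: `moments` (data.frame, one row
#'   per model), `pp` (named list of P-P coordinate data.frames),
#'   `crossCorrelation` (see [residualCrossCorrelation()]), `n`.
#' @export
residualReport <- function(table, library, alpha = 0.05, multiplier = 2) {
  res <- residualMatrix(table, library)
  sigmas <- vapply(table@models, function(m) m@fit$sigma, numeric(1))
  momentRows <- lapply(colnames(res), function(key) {
    m <- residualMoments(res[, key], multiplier = multiplier)
    data.frame(mz = as.integer(key), skewness = m$skewness,
               se.skew = m$se.skew, skew.significant = m$skew.significant,
               excess.kurtosis = m$excess.kurtosis,
               se.kurtosis = m$se.kurtosis,
               kurtosis.significant = m$kurtosis.significant)
  })
  pp <- lapply(colnames(res), function(key)
    ppCoordinates(res[, key] / sigmas[[key]]))
  names(pp) <- colnames(res)
  structure(list(
    moments = do.call(rbind, momentRows),
    pp = pp,
    crossCorrelation = residualCrossCorrelation(res, alpha = alpha),
    n = nrow(res)), class = "ResidualReport")
}

#' @export
print.ResidualReport <- function(x, ...) {
  cat(sprintf("ResidualReport over %d spectra, %d models\n",
              x$n, nrow(x$moments)))
  cat(sprintf("  significant skew: %d/%d models; significant kurtosis: %d/%d\n",
              sum(x$moments$skew.significant), nrow(x$moments),
              sum(x$moments$kurtosis.significant), nrow(x$moments)))
  cat(sprintf("  residual pairs significant at alpha = %.2g: %.1f%% of %d\n",
              x$crossCorrelation$alpha,
              100 * x$crossCorrelation$fractionSignificant,
              x$crossCorrelation$nPairs))
  invisible(x)
}
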