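## Core ordinary-least-squares machinery for the per-ion models.
## Fitting goes through base lm.fit (QR); this file packages the summary
## quantities the coefficient table needs and the partial-F bookkeeping the
## stepwise selector is built on.

#' Ordinary least squares fit with model summary
#'
#' Fits `y = b0 + X b + e` by QR least squares and returns the quantities a
#' coefficient table needs: estimates, standard errors, residual degrees of
#' freedom and standard deviation, R-squared, the overall F test, and
#' standardized coefficients (`b * sd(x) / sd(y)`).
#'
#' @param y numeric response vector.
#' @param X numeric covariate matrix (columns named; may have 0 columns for
#'   an intercept-only fit).
#' @return list with elements `coefficients`, `se`, `df`, `sigma`,
#'   `r.squared`, `fstatistic`, `f.pvalue`, `std.coefficients`, `n`,
#'   `mean.y`, `mean.x`, `residuals`, `fitted`.
#' @export
fitOls <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("rows(X) must equal length(y)")
  p <- ncol(X)
  if (n <= p + 1L)
    stop("need n > p + 1 observations (n = ", n, ", p = ", p, ")")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) {
    dep <- colnames(Xd)[qrx$pivot[seq(qrx$rank + 1L, ncol(Xd))]]
    stop("rank-deficient design matrix; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xd %*% beta)
  res <- y - fitted
  df <- n - p - 1L
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- names(beta)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  if (p > 0 && tss > 0 && rss > 0) {
    f <- (tss - rss) / p / sigma2
    fp <- stats::pf(f, p, df, lower.tail = FALSE)
  } else if (p > 0 && tss > 0) {
    f <- Inf; fp <- 0
  } else {
    f <- NA_real_; fp <- NA_real_
  }
  sdy <- stats::sd(y)
  stdb <- if (p > 0 && sdy > 0)
    beta[-1L] * apply(X, 2, stats::sd) / sdy else stats::setNames(numeric(0), NULL)
  list(coefficients = beta, se = se, df = df, sigma = sqrt(sigma2),
       r.squared = r2, fstatistic = f, f.pvalue = fp,
       std.coefficients = stdb, n = n,
       mean.y = mean(y),
       mean.x = if (p > 0) colMeans(X) else numeric(0),
       residuals = res, fitted = fitted)
}

## Residual sum of squares of the least-squares fit of y on [1, X];
## returns the effective rank alongside so callers can detect collinearity.
.rssOf <- function(y, X) {
  Xd <- cbind(1, X)
  fit <- stats::lm.fit(Xd, y)
  list(rss = sum(fit$residuals^2), rank = fit$rank, p = ncol(Xd) - 1L)
}

#' Partial F test p-value for one added or removed covariate
#'
#' Compares the nested OLS models with and without a single candidate column
#' via the change in residual sum of squares with 1 numerator degree of
#' freedom. With 1 df the F statistic equals the square of the candidate's t
#' statistic in the larger model.
#'
#' @param y response vector.
#' @param Xcurrent matrix of covariates currently in the model (may have 0
#'   columns).
#' @param xCandidate the candidate covariate column.
#' @param action `"add"` (candidate not in the current model) or `"remove"`
#'   (candidate is a column of `Xcurrent` to drop).
#' @return p-value in [0, 1] with attributes `F` (the statistic) and
#'   `degenerate` (TRUE when the candidate is collinear with the current
#'   model, in which case p = 1). A candidate explaining all remaining
#'   residual variance yields p = 0.
#' @export
partialFPValue <- function(y, Xcurrent, xCandidate, action = c("add", "remove")) {
  action <- match.arg(action)
  Xcurrent <- as.matrix(Xcurrent)
  if (action == "add") {
    small <- .rssOf(y, Xcurrent)
    Xbig <- cbind(Xcurrent, xCandidate)
    big <- .rssOf(y, Xbig)
    if (big$rank < ncol(Xbig) + 1L) {   # candidate adds nothing to the span
      p <- 1
      attr(p, "F") <- 0
      attr(p, "degenerate") <- TRUE
      return(p)
    }
  } else {
    big <- .rssOf(y, Xcurrent)
    keep <- !vapply(seq_len(ncol(Xcurrent)), function(j)
      isTRUE(all.equal(Xcurrent[, j], xCandidate)), logical(1))
    if (all(keep)) stop("candidate to remove is not in the current model")
    small <- .rssOf(y, Xcurrent[, keep, drop = FALSE])
    Xbig <- Xcurrent
  }
  n <- length(y)
  dfBig <- n - big$p - 1L
  if (dfBig < 1L) stop("no residual degrees of freedom in the larger model")
  dRss <- small$rss - big$rss
  if (big$rss <= max(1e-12 * small$rss, 1e-300)) {
    ## larger model is (numerically) saturated: the term is decisive
    p <- if (dRss > 0) 0 else 1
    attr(p, "F") <- if (dRss > 0) Inf else 0
    attr(p, "degenerate") <- dRss <= 0
    return(p)
  }
  f <- dRss / (big$rss / dfBig)
  f <- max(f, 0)
  p <- stats::pf(f, 1, dfBig, lower.tail = FALSE)
  attr(p, "F") <- f
  attr(p, "degenerate") <- FALSE
  p
}
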