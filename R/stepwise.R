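## Mixed stepwise covariate selection, the heart of the identification
## pipeline: each panel ion is modeled on the remaining panel ions, entering
## the most significant candidate (partial-F p <= pEnter) and removing the
## least significant included term (p >= pRemove) until the model is stable.

.COND_GUARD <- 1e-10   # reciprocal-condition-number floor for candidate entry
.MAX_STEPS <- 100L     # hard cap against pathological cycling

## A candidate may enter only if the augmented design stays numerically
## full rank (reciprocal condition number >= .COND_GUARD).
.candidateEligible <- function(Xcur, xc) {
  Xtry <- cbind(1, Xcur, xc)
  qrx <- qr(Xtry)
  if (qrx$rank < ncol(Xtry)) return(FALSE)
  R <- qr.R(qrx)
  rcond(R) >= .COND_GUARD
}

#' Mixed stepwise selection of one per-ion model
#'
#' Builds the general linear model for one dependent panel ion using the
#' other panel ions as candidate covariates. Candidates are entered when
#' their partial-F p-value is the smallest among eligible candidates and
#' `<= pEnter`; after each entry, included covariates whose removal
#' partial-F p is the largest and `>= pRemove` are dropped, until neither
#' rule fires. Ties are broken toward the lower m/z. `pEnter < pRemove` is
#' required (it rules out immediate enter/remove cycles).
#'
#' @param yMz the dependent ion (nominal mass, must be a matrix column).
#' @param matrix abundance matrix from [buildAbundanceMatrix()] (columns
#'   named by m/z).
#' @param pEnter entry threshold on the probability of F (default 0.05).
#' @param pRemove removal threshold (default 0.10).
#' @param candidates optional integer vector restricting the candidate pool
#'   (defaults to all other columns).
#' @return an [IonModel-class], or an object of class `"ionModelSkip"`
#'   (fields `dependentMz`, `reason`) when the dependent column is constant.
#' @export
stepwiseSelect <- function(yMz, matrix, pEnter = 0.05, pRemove = 0.10,
                           candidates = NULL) {
  if (pEnter >= pRemove)
    stop("pEnter must be < pRemove (got ", pEnter, " >= ", pRemove, ")")
  cols <- as.integer(colnames(matrix))
  yMz <- as.integer(yMz)
  if (!yMz %in% cols) stop("dependent m/z ", yMz, " is not a matrix column")
  y <- matrix[, as.character(yMz)]
  if (stats::var(y) == 0)
    return(structure(list(dependentMz = yMz, reason = "zero-variance dependent"),
                     class = "ionModelSkip"))
  if (is.null(candidates)) candidates <- setdiff(cols, yMz)
  candidates <- sort(as.integer(setdiff(candidates, yMz)))
  ## drop constant candidates outright
  candidates <- candidates[apply(matrix[, as.character(candidates), drop = FALSE],
                                 2, stats::var) > 0]
  included <- integer(0)
  trace <- list()
  step <- 0L
  repeat {
    if (step >= .MAX_STEPS) break
    changed <- FALSE
    Xcur <- matrix[, as.character(included), drop = FALSE]
    ## ---- entry ----
    pool <- setdiff(candidates, included)
    if (length(pool) && length(y) > length(included) + 2L) {
      ps <- rep(NA_real_, length(pool))
      for (i in seq_along(pool)) {
        xc <- matrix[, as.character(pool[i])]
        if (!.candidateEligible(Xcur, xc)) next
        ps[i] <- as.numeric(partialFPValue(y, Xcur, xc, "add"))
      }
      if (any(!is.na(ps))) {
        ord <- order(ps, pool, na.last = TRUE)
        best <- ord[1L]
        if (!is.na(ps[best]) && ps[best] <= pEnter) {
          included <- c(included, pool[best])
          step <- step + 1L
          trace[[length(trace) + 1L]] <-
            data.frame(step = step, action = "enter", mz = pool[best],
                       p = ps[best])
          changed <- TRUE
        }
      }
    }
    ## ---- removal sweep ----
    repeat {
      if (length(included) < 1L) break
      Xcur <- matrix[, as.character(included), drop = FALSE]
      ps <- vapply(seq_along(included), function(j)
        as.numeric(partialFPValue(y, Xcur, Xcur[, j], "remove")),
        numeric(1))
      ord <- order(-ps, included)
      worst <- ord[1L]
      if (ps[worst] >= pRemove) {
        step <- step + 1L
        trace[[length(trace) + 1L]] <-
          data.frame(step = step, action = "remove", mz = included[worst],
                     p = ps[worst])
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  X <- matrix[, as.character(included), drop = FALSE]
  fit <- fitOls(y, X)
  new("IonModel", dependentMz = yMz, covariateMz = as.integer(included),
      fit = fit,
      trace = if (length(trace)) do.call(rbind, trace)
              else data.frame(step = integer(0), action = character(0),
                              mz = integer(0), p = numeric(0)))
}

#' Predict one ion's abundance in a query spectrum
#'
#' Evaluates `A-hat = b0 + sum(bj * xj)` with `xj` the query's normalized
#' abundance of covariate ion j. A covariate absent from the query
#' contributes 0 (with a warning). Predictions are not clamped to
#' [0, 100]: out-of-range predictions are diagnostic signal.
#'
#' @param model an [IonModel-class].
#' @param query a normalized [Spectrum-class].
#' @return predicted abundance (% of base peak), a single numeric.
#' @export
predictIon <- function(model, query) {
  stopifnot(is(model, "IonModel"), is(query, "Spectrum"))
  if (!isTRUE(query@normalized))
    stop("query spectrum must be normalized before prediction")
  beta <- model@fit$coefficients
  xhat <- beta[["(Intercept)"]]
  if (length(model@covariateMz)) {
    keys <- as.character(model@covariateMz)
    x <- query@peaks[keys]
    missing <- keys[is.na(x)]
    if (length(missing))
      warning("query '", query@id, "' lacks covariate ion(s) m/z ",
              paste(missing, collapse = ", "), "; using abundance 0")
    x[is.na(x)] <- 0
    xhat <- xhat + sum(beta[keys] * x)
  }
  unname(xhat)
}

#' Predict all panel ions for a query spectrum
#'
#' Applies every non-skipped per-ion model in the coefficient table to one
#' query spectrum and reports, per ion: the predicted abundance, the
#' measured abundance (0 when the ion is absent), the raw residual
#' (measured minus predicted), and the standardized residual (raw residual
#' divided by that model's training residual standard deviation).
#'
#' @param table a [CoefficientTable-class].
#' @param query a normalized [Spectrum-class].
#' @return data.frame with columns `mz`, `predicted`, `measured`,
#'   `residual`, `std.residual`; one row per modeled panel ion.
#' @export
predictAll <- function(table, query) {
  stopifnot(is(table, "CoefficientTable"))
  rows <- lapply(table@models, function(m) {
    pred <- predictIon(m, query)
    key <- as.character(m@dependentMz)
    meas <- if (key %in% names(query@peaks)) query@peaks[[key]] else 0
    res <- meas - pred
    data.frame(mz = m@dependentMz, predicted = pred, measured = meas,
               residual = res, std.residual = res / m@fit$sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
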