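#' Train a full coefficient table from a replicate library
#'
#' Runs the complete training pipeline: select the ion panel (most abundant
#' ions, plus any forced inclusions), build the abundance matrix, and fit one
#' mixed-stepwise general linear model per panel ion with the other panel
#' ions as candidate covariates. Degenerate (exactly constant) dependent
#' ions get a skip record instead of a model.
#'
#' @param library a normalized [SpectrumLibrary-class] of replicate spectra.
#' @param nIons panel size (default 20).
#' @param pEnter,pRemove stepwise thresholds on the probability of F
#'   (defaults 0.05 / 0.10).
#' @param forceInclude integer m/z values guaranteed a panel slot.
#' @return a [CoefficientTable-class].
#' @export
trainCoefficientTable <- function(library, nIons = 20, pEnter = 0.05,
                                  pRemove = 0.10, forceInclude = integer(0)) {
  stopifnot(is(library, "SpectrumLibrary"))
  if (length(library) <= nIons + 2L)
    stop("need more than nIons + 2 = ", nIons + 2L, " spectra (have ",
         length(library), ")")
  panel <- selectTopIons(library, n = nIons, forceInclude = forceInclude)
  mat <- buildAbundanceMatrix(library, panel)
  models <- list()
  skips <- list()
  for (mz in panel@mz) {
    m <- stepwiseSelect(mz, mat, pEnter = pEnter, pRemove = pRemove)
    if (inherits(m, "ionModelSkip")) skips[[as.character(mz)]] <- m$reason
    else models[[as.character(mz)]] <- m
  }
  new("CoefficientTable", panel = panel, models = models, skips = skips,
      provenance = list(
        compound = library@compound, n = length(library),
        date = format(Sys.Date()), pEnter = pEnter, pRemove = pRemove,
        forceInclude = as.integer(forceInclude)))
}

#' Serialize / restore a coefficient table (JSON)
#'
#' The JSON carries the full deployable artifact: panel, per-model
#' coefficients with standard errors, residual SD, R-squared, the selection
#' trace, skip records and training provenance. [readCoefficientTable()]
#' restores an equivalent [CoefficientTable-class].
#'
#' @param table a [CoefficientTable-class].
#' @param path output / input JSON path.
#' @return write: `path`, invisibly; read: a [CoefficientTable-class].
#' @export
writeCoefficientTable <- function(table, path) {
  stopifnot(is(table, "CoefficientTable"))
  obj <- list(
    panel = list(mz = table@panel@mz, score = table@panel@score),
    provenance = table@provenance,
    skips = table@skips,
    models = lapply(table@models, function(m) {
      f <- m@fit
      list(dependentMz = m@dependentMz,
           covariateMz = m@covariateMz,
           coefficients = as.list(f$coefficients),
           se = as.list(f$se),
           df = f$df, sigma = f$sigma, r.squared = f$r.squared,
           fstatistic = f$fstatistic, f.pvalue = f$f.pvalue,
           std.coefficients = as.list(f$std.coefficients),
           n = f$n, mean.y = f$mean.y, mean.x = as.list(f$mean.x),
           trace = m@trace)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeCoefficientTable
#' @export
readCoefficientTable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  panel <- new("IonPanel", mz = as.integer(obj$panel$mz),
               score = as.numeric(obj$panel$score))
  models <- lapply(obj$models, function(m) {
    tr <- m$trace
    trace <- if (length(tr$step))
      data.frame(step = as.integer(tr$step), action = as.character(tr$action),
                 mz = as.integer(tr$mz), p = as.numeric(tr$p))
    else data.frame(step = integer(0), action = character(0),
                    mz = integer(0), p = numeric(0))
    fit <- list(
      coefficients = unlist(m$coefficients),
      se = unlist(m$se),
      df = as.integer(m$df), sigma = m$sigma, r.squared = m$r.squared,
      fstatistic = m$fstatistic, f.pvalue = m$f.pvalue,
      std.coefficients = if (length(m$std.coefficients))
        unlist(m$std.coefficients) else numeric(0),
      n = as.integer(m$n), mean.y = m$mean.y,
      mean.x = if (length(m$mean.x)) unlist(m$mean.x) else numeric(0))
    new("IonModel", dependentMz = as.integer(m$dependentMz),
        covariateMz = as.integer(unlist(m$covariateMz)),
        fit = fit, trace = trace)
  })
  names(models) <- vapply(models, function(m) as.character(m@dependentMz),
                          character(1))
  skips <- lapply(obj$skips, as.character)
  prov <- obj$provenance
  prov$forceInclude <- as.integer(unlist(prov$forceInclude))
  new("CoefficientTable", panel = panel, models = models,
      skips = skips, provenance = prov)
}

#' Export the coefficient table as flat CSV
#'
#' One row per dependent m/z; columns are the intercept followed by every
#' panel m/z. Cells of unselected covariates are empty; the last columns
#' carry each model's R-squared and residual SD.
#'
#' @param table a [CoefficientTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCoefficientCSV <- function(table, path) {
  mzs <- table@panel@mz
  rows <- lapply(as.character(mzs), function(key) {
    row <- stats::setNames(rep(NA_real_, length(mzs) + 3L),
                           c("(Intercept)", as.character(mzs),
                             "r.squared", "sigma"))
    if (!is.null(table@models[[key]])) {
      m <- table@models[[key]]
      b <- m@fit$coefficients
      row[names(b)] <- b
      row["r.squared"] <- m@fit$r.squared
      row["sigma"] <- m@fit$sigma
    }
    row
  })
  df <- data.frame(dependent.mz = mzs, do.call(rbind, rows),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
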