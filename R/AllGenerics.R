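#' Accessors for easiMS classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an easiMS S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))

#' @rdname accessors
#' @export
setGeneric("spectrumIds", function(object) standardGeneric("spectrumIds"))

#' @rdname accessors
#' @export
setGeneric("compoundName", function(object) standardGeneric("compoundName"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("panelMz", function(object) standardGeneric("panelMz"))

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("pathways", function(object) standardGeneric("pathways"))

#' @rdname accessors
#' @export
setGeneric("ionModels", function(object) standardGeneric("ionModels"))

#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(object) standardGeneric("modelCoefficients"))

#' Normalize abundances to the base peak
#'
#' Scales abundances so the most abundant peak (the base peak) is exactly 100;
#' all other abundances become percentages of it. Applied to a library it
#' normalizes every member spectrum. Normalization is idempotent.
#'
#' When two or more peaks tie for the maximum abundance, the lowest m/z is
#' annotated as the base peak; the scaling itself is unaffected by the tie.
#'
#' @param object a [Spectrum-class] or [SpectrumLibrary-class].
#' @return an object of the same class, normalized.
#' @export
setGeneric("normalizeToBasePeak", function(object) standardGeneric("normalizeToBasePeak"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("peaks", "Spectrum", function(object) object@peaks)

#' @rdname accessors
#' @export
setMethod("spectrumId", "Spectrum", function(object) object@id)

#' @rdname accessors
#' @export
setMethod("spectrumIds", "SpectrumLibrary",
  function(object) vapply(object@spectra, function(s) s@id, character(1)))

#' @rdname accessors
#' @export
setMethod("compoundName", "SpectrumLibrary", function(object) object@compound)

#' @rdname accessors
#' @export
setMethod("isNormalized", "Spectrum", function(object) isTRUE(object@normalized))

#' @rdname accessors
#' @export
setMethod("isNormalized", "SpectrumLibrary",
  function(object) all(vapply(object@spectra, function(s) isTRUE(s@normalized), logical(1))))

#' @rdname accessors
#' @export
setMethod("panelMz", "IonPanel", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("panelMz", "CoefficientTable", function(object) object@panel@mz)

#' @rdname accessors
#' @export
setMethod("speciesNames", "FragmentationNetwork", function(object) object@species)

#' @rdname accessors
#' @export
setMethod("pathways", "FragmentationNetwork", function(object)
  data.frame(parent = object@parent, product = object@product,
             E0 = object@E0, v = object@v, stringsAsFactors = FALSE))

#' @rdname accessors
#' @export
setMethod("ionModels", "CoefficientTable", function(object) object@models)

#' @rdname accessors
#' @export
setMethod("modelCoefficients", "IonModel", function(object) object@fit$coefficients)

setMethod("length", "SpectrumLibrary", function(x) length(x@spectra))

setMethod("length", "IonPanel", function(x) length(x@mz))

#' Extract a spectrum from a library
#'
#' @param x a [SpectrumLibrary-class].
#' @param i index or spectrum id.
#' @export
setMethod("[[", "SpectrumLibrary", function(x, i) {
  if (is.character(i)) i <- match(i, spectrumIds(x))
  x@spectra[[i]]
})

## ---- show ----------------------------------------------------------------

setMethod("show", "Spectrum", function(object) {
  p <- object@peaks
  cat(sprintf("Spectrum '%s' (%s): %d peaks%s\n", object@id, object@label,
              length(p), if (isTRUE(object@normalized)) ", normalized" else ""))
  if (length(p)) {
    bp <- names(p)[which(p == max(p))]
    cat(sprintf("  base peak m/z %s; m/z range %s-%s\n",
                bp[1L], min(as.integer(names(p))), max(as.integer(names(p)))))
  }
  invisible(NULL)
})

setMethod("show", "SpectrumLibrary", function(object) {
  cat(sprintf("SpectrumLibrary of %d spectra (compound: %s)%s\n",
              length(object@spectra), object@compound,
              if (isNormalized(object)) ", normalized" else ""))
  invisible(NULL)
})

setMethod("show", "IonPanel", function(object) {
  cat(sprintf("IonPanel of %d ions: %s\n", length(object@mz),
              paste(object@mz, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "FragmentationNetwork", function(object) {
  cat(sprintf("FragmentationNetwork: precursor %s (%d atoms), %d species, %d pathways\n",
              object@precursor, object@atoms[[object@precursor]],
              length(object@species), length(object@parent)))
  pw <- pathways(object)
  if (nrow(pw))
    cat(sprintf("  %s -> %s  (E0 = %.2f eV, v = %.2e /s)\n",
                pw$parent, pw$product, pw$E0, pw$v), sep = "")
  invisible(NULL)
})

setMethod("show", "BreakdownCurve", function(object) {
  cat(sprintf("BreakdownCurve (%s mode, fixed = %g): %d grid points x %d species\n",
              object@mode, object@fixed, length(object@axis), ncol(object@fractions)))
  invisible(NULL)
})

setMethod("show", "IonModel", function(object) {
  cat(sprintf("IonModel for m/z %d: %d covariates (R^2 = %.4f)\n",
              object@dependentMz, length(object@covariateMz),
              object@fit$r.squared))
  if (length(object@covariateMz))
    cat("  covariates: m/z", paste(object@covariateMz, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CoefficientTable", function(object) {
  cat(sprintf("CoefficientTable: %d-ion panel, %d models, %d skipped (n = %s, compound: %s)\n",
              length(object@panel@mz), length(object@models),
              length(object@skips),
              as.character(object@provenance$n %||% NA),
              as.character(object@provenance$compound %||% NA)))
  invisible(NULL)
})

setMethod("show", "LabProfile", function(object) {
  cat(sprintf(
    "LabProfile '%s': E ~ N(%.3g, %.3g) eV, log t ~ N(%.3g, %.3g), noise CV %.3g, n = %d, seed = %d\n",
    object@name, object@energyMean, object@energySpread,
    object@logTimeMean, object@logTimeSpread, object@noiseCV,
    object@n, object@seed))
  invisible(NULL)
})

setMethod("show", "LinearTruth", function(object) {
  cat(sprintf("LinearTruth: %d-ion panel, %d ions loaded on factor 1, %d on factor 2\n",
              length(object@mz), sum(object@loading != 0), sum(object@loading2 != 0)))
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
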