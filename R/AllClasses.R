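#' @import methods
NULL

#' Spectrum: a single nominal-mass EI peak list
#'
#' A centroided, nominal-mass electron-ionization mass spectrum. Peaks are
#' stored as a named numeric vector (names are integer m/z values). A spectrum
#' is *normalized* when its largest abundance is exactly 100 (percent of the
#' base peak); raw spectra as read from an MSP file are not yet normalized.
#'
#' @slot id character(1) spectrum identifier (from the MSP `Name:` field).
#' @slot label character(1) class tag: `"known-positive"`, `"known-negative"`
#'   or `"unlabeled"`.
#' @slot source character(1) free-text laboratory / instrument tag.
#' @slot peaks named numeric vector of non-negative abundances; names are the
#'   nominal m/z values (unique integers >= 1).
#' @slot normalized logical(1); TRUE once scaled so the base peak is 100.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    id = "character",
    label = "character",
    source = "character",
    peaks = "numeric",
    normalized = "logical"
  ),
  prototype(
    id = NA_character_, label = "unlabeled", source = "",
    peaks = numeric(0), normalized = FALSE
  )
)

setValidity("Spectrum", function(object) {
  msg <- character(0)
  p <- object@peaks
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (!object@label %in% c("known-positive", "known-negative", "unlabeled"))
    msg <- c(msg, "'label' must be known-positive, known-negative or unlabeled")
  if (length(p)) {
    mz <- suppressWarnings(as.numeric(names(p)))
    if (anyNA(mz) || any(mz < 1) || any(mz != round(mz)))
      msg <- c(msg, "peak names must be integer m/z values >= 1")
    if (anyDuplicated(mz))
      msg <- c(msg, "m/z values must be unique")
    if (any(!is.finite(p)) || any(p < 0))
      msg <- c(msg, "abundances must be finite and non-negative")
    if (isTRUE(object@normalized)) {
      if (abs(max(p) - 100) > 1e-9)
        msg <- c(msg, "normalized spectrum must have base peak abundance 100")
      if (any(p > 100 + 1e-9))
        msg <- c(msg, "normalized abundances must lie in [0, 100]")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpectrumLibrary: an ordered collection of replicate spectra
#'
#' @slot spectra list of [Spectrum-class] objects with unique ids.
#' @slot compound character(1) compound name the replicates represent.
#'
#' @exportClass SpectrumLibrary
setClass("SpectrumLibrary",
  representation(spectra = "list", compound = "character"),
  prototype(spectra = list(), compound = NA_character_)
)

setValidity("SpectrumLibrary", function(object) {
  msg <- character(0)
  if (!length(object@spectra))
    msg <- c(msg, "library must contain at least one spectrum")
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    msg <- c(msg, "all elements of 'spectra' must be Spectrum objects")
  else {
    ids <- vapply(object@spectra, function(s) s@id, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "spectrum ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' IonPanel: the ordered set of modeled fragment ions
#'
#' The panel of nominal masses retained for modeling, ordered by decreasing
#' selection score (mean normalized abundance across the training library,
#' ties broken by lower m/z).
#'
#' @slot mz integer vector of distinct nominal masses, in panel order.
#' @slot score numeric vector of selection scores aligned with `mz`.
#'
#' @exportClass IonPanel
setClass("IonPanel",
  representation(mz = "integer", score = "numeric"),
  prototype(mz = integer(0), score = numeric(0))
)

setValidity("IonPanel", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@mz)) msg <- c(msg, "panel m/z values must be distinct")
  if (length(object@mz) != length(object@score))
    msg <- c(msg, "'mz' and 'score' must have equal length")
  if (any(object@mz < 1)) msg <- c(msg, "panel m/z values must be >= 1")
  if (length(msg)) msg else TRUE
})

#' FragmentationNetwork: competitive/sequential unimolecular pathways
#'
#' A rooted directed acyclic graph of dissociation pathways. Each pathway has
#' a critical (activation) energy `E0` in eV and a frequency factor `v` in
#' s^-1; rates follow the Kassel form with the parent's atom count setting the
#' vibrational degrees of freedom.
#'
#' @slot precursor character(1) name of the precursor species (the root).
#' @slot species character vector of all species names (precursor first is not
#'   required; order is free).
#' @slot atoms named integer vector: atom count per species (>= 3 for any
#'   species that fragments further).
#' @slot mass named integer vector: nominal mass per species, used when
#'   simulated abundances are rendered as spectra.
#' @slot parent,product character vectors defining pathway edges.
#' @slot E0 numeric vector of critical energies (eV), one per pathway.
#' @slot v numeric vector of frequency factors (s^-1), one per pathway.
#'
#' @exportClass FragmentationNetwork
setClass("FragmentationNetwork",
  representation(
    precursor = "character", species = "character",
    atoms = "integer", mass = "integer",
    parent = "character", product = "character",
    E0 = "numeric", v = "numeric"
  )
)

.topo_order <- function(species, parent, product) {
  ## Kahn's algorithm; returns NULL if the edge set is cyclic.
  indeg <- stats::setNames(integer(length(species)), species)
  for (p in product) indeg[p] <- indeg[p] + 1L
  queue <- species[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    out <- c(out, n)
    kids <- product[parent == n]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) == length(species)) out else NULL
}

setValidity("FragmentationNetwork", function(object) {
  msg <- character(0)
  sp <- object@species
  if (!object@precursor %in% sp) msg <- c(msg, "precursor must be listed in species")
  if (anyDuplicated(sp)) msg <- c(msg, "species names must be unique")
  np <- length(object@parent)
  if (length(object@product) != np || length(object@E0) != np ||
      length(object@v) != np)
    msg <- c(msg, "parent, product, E0 and v must have equal length")
  if (!all(object@parent %in% sp) || !all(object@product %in% sp))
    msg <- c(msg, "pathway endpoints must be listed species")
  if (any(object@E0 <= 0)) msg <- c(msg, "all E0 must be > 0")
  if (any(object@v <= 0)) msg <- c(msg, "all v must be > 0")
  if (!all(sp %in% names(object@atoms)))
    msg <- c(msg, "atom counts must cover every species")
  if (!all(sp %in% names(object@mass)))
    msg <- c(msg, "nominal masses must cover every species")
  if (!length(msg)) {
    if (object@atoms[[object@precursor]] < 3L)
      msg <- c(msg, "precursor atom count must be >= 3")
    ord <- .topo_order(sp, object@parent, object@product)
    if (is.null(ord))
      msg <- c(msg, "pathways must form a DAG")
    else {
      reach <- object@precursor
      repeat {
        nxt <- unique(c(reach, object@product[object@parent %in% reach]))
        if (length(nxt) == length(reach)) break
        reach <- nxt
      }
      if (!all(sp %in% reach))
        msg <- c(msg, "every species must be reachable from the precursor")
    }
  }
  if (length(msg)) msg else TRUE
})

#' BreakdownCurve: fractional species abundances over a grid
#'
#' @slot mode `"time"` or `"energy"`: the axis that varies.
#' @slot fixed numeric(1): the held value (internal energy in eV for a time
#'   curve, observation time in s for an energy curve).
#' @slot axis numeric grid (s or eV), strictly increasing.
#' @slot fractions numeric matrix, `length(axis)` x species; rows sum to 1.
#'
#' @exportClass BreakdownCurve
setClass("BreakdownCurve",
  representation(
    mode = "character", fixed = "numeric",
    axis = "numeric", fractions = "matrix"
  )
)

setValidity("BreakdownCurve", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("time", "energy"))
    msg <- c(msg, "'mode' must be 'time' or 'energy'")
  if (length(object@axis) != nrow(object@fractions))
    msg <- c(msg, "axis length must equal nrow(fractions)")
  if (is.unsorted(object@axis, strictly = TRUE))
    msg <- c(msg, "axis must be strictly increasing")
  fr <- object@fractions
  if (any(fr < -1e-10) || any(fr > 1 + 1e-10))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (nrow(fr) && any(abs(rowSums(fr) - 1) > 1e-8))
    msg <- c(msg, "species fractions must sum to 1 at every grid point")
  if (length(msg)) msg else TRUE
})

#' IonModel: one per-ion general linear model
#'
#' The stepwise-selected ordinary-least-squares model for a single dependent
#' panel ion, with the remaining panel ions as candidate covariates.
#'
#' @slot dependentMz integer(1) the modeled ion.
#' @slot covariateMz integer vector of selected covariate ions (may be empty).
#' @slot fit list with the OLS summary: `coefficients`, `se`, `df`,
#'   `sigma` (residual standard deviation), `r.squared`, `fstatistic`,
#'   `f.pvalue`, `std.coefficients`, `n`, and the training means
#'   (`mean.y`, `mean.x`).
#' @slot trace data.frame of the selection path: step, action
#'   (`"enter"`/`"remove"`), mz, p.
#'
#' @exportClass IonModel
setClass("IonModel",
  representation(
    dependentMz = "integer", covariateMz = "integer",
    fit = "list", trace = "data.frame"
  )
)

setValidity("IonModel", function(object) {
  msg <- character(0)
  if (length(object@dependentMz) != 1L)
    msg <- c(msg, "'dependentMz' must be a single m/z")
  if (object@dependentMz %in% object@covariateMz)
    msg <- c(msg, "the dependent ion cannot be its own covariate")
  if (anyDuplicated(object@covariateMz))
    msg <- c(msg, "covariate m/z values must be distinct")
  if (length(msg)) msg else TRUE
})

#' CoefficientTable: the deployable set of per-ion models
#'
#' One [IonModel-class] per panel ion (or a skip record with a reason for
#' degenerate ions), plus training provenance. This object is the portable
#' identification artifact: predicting a query spectrum needs only these
#' coefficients, never the training spectra themselves.
#'
#' @slot panel [IonPanel-class] the modeled ions.
#' @slot models named list of [IonModel-class], names are dependent m/z.
#' @slot skips named list of skip reasons (character) for unmodeled ions.
#' @slot provenance list: compound, n (training spectra), date, pEnter,
#'   pRemove, forceInclude.
#'
#' @exportClass CoefficientTable
setClass("CoefficientTable",
  representation(
    panel = "IonPanel", models = "list",
    skips = "list", provenance = "list"
  )
)

setValidity("CoefficientTable", function(object) {
  msg <- character(0)
  k <- length(object@panel@mz)
  if (length(object@models) + length(object@skips) != k)
    msg <- c(msg, "models plus skips must cover the panel exactly")
  covered <- c(names(object@models), names(object@skips))
  if (!setequal(covered, as.character(object@panel@mz)))
    msg <- c(msg, "model/skip names must match the panel m/z values")
  if (length(msg)) msg else TRUE
})

#' LabProfile: acquisition conditions for one simulated laboratory
#'
#' Parameterizes the latent internal-energy and observation-time distributions
#' of a simulated instrument, plus per-ion multiplicative measurement noise.
#'
#' @slot energyMean,energySpread numeric(1): mean and SD of internal energy (eV).
#' @slot logTimeMean,logTimeSpread numeric(1): mean and SD of log observation
#'   time (time in s; log-normal across replicates).
#' @slot noiseCV numeric(1) coefficient of variation of the multiplicative
#'   log-normal measurement noise applied independently per ion.
#' @slot n integer(1) number of replicate spectra to draw.
#' @slot seed integer(1) RNG seed.
#' @slot name character(1) laboratory tag stamped into each spectrum's source.
#'
#' @exportClass LabProfile
setClass("LabProfile",
  representation(
    energyMean = "numeric", energySpread = "numeric",
    logTimeMean = "numeric", logTimeSpread = "numeric",
    noiseCV = "numeric", n = "integer", seed = "integer",
    name = "character"
  )
)

setValidity("LabProfile", function(object) {
  msg <- character(0)
  if (object@energySpread <= 0 || object@logTimeSpread <= 0)
    msg <- c(msg, "energy and log-time spreads must be > 0")
  if (object@noiseCV < 0) msg <- c(msg, "noise CV must be >= 0")
  if (object@n < 3L) msg <- c(msg, "a lab profile must draw at least 3 spectra")
  if (length(msg)) msg else TRUE
})

#' LinearTruth: generating parameters for a linear synthetic library
#'
#' A one-factor (optionally two-factor) linear generative model for panel-ion
#' abundances: `abundance(i, j) = mean_j + loading_j * f_i + noise`, with
#' `f_i` standard normal. Used to build spectral libraries with *known*
#' linear structure so that fitted coefficients can be compared to truth.
#'
#' @slot mz integer vector: the k panel ions.
#' @slot mean numeric vector: per-ion mean normalized abundance.
#' @slot loading numeric vector: per-ion latent-factor loading.
#' @slot loading2 numeric vector: optional second-factor loading (zeros by
#'   default).
#' @slot noiseSD numeric vector: per-ion measurement-noise SD (abundance
#'   units, %% of base peak).
#'
#' @exportClass LinearTruth
setClass("LinearTruth",
  representation(
    mz = "integer", mean = "numeric", loading = "numeric",
    loading2 = "numeric", noiseSD = "numeric"
  )
)

setValidity("LinearTruth", function(object) {
  msg <- character(0)
  k <- length(object@mz)
  if (length(object@mean) != k || length(object@loading) != k ||
      length(object@loading2) != k || length(object@noiseSD) != k)
    msg <- c(msg, "mean, loading, loading2 and noiseSD must match length(mz)")
  if (any(object@noiseSD < 0)) msg <- c(msg, "noise SDs must be >= 0")
  if (anyDuplicated(object@mz)) msg <- c(msg, "panel m/z values must be distinct")
  lo <- object@mean - 3 * (abs(object@loading) + abs(object@loading2))
  hi <- object@mean + 3 * (abs(object@loading) + abs(object@loading2))
  if (any(lo < -1e-9) || any(hi > 100 + 1e-9))
    msg <- c(msg, "implied abundances must stay within [0, 100] at +/-3 latent SD")
  if (length(msg)) msg else TRUE
})
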