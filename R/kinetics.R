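#' Kassel microcanonical rate constant
#'
#' Classical Kassel approximation to the RRKM dissociation rate:
#' `k(E) = v * ((E - E0) / E)^(3N - 7)` for `E > E0`, and 0 otherwise.
#' `3N - 7` is the number of vibrational degrees of freedom of a nonlinear
#' precursor, excluding the reaction coordinate. The rate is nondecreasing in
#' the internal energy `E` and approaches the frequency factor `v` as
#' `E -> Inf`; larger precursors (larger `N`) dissociate more slowly at the
#' same excess energy.
#'
#' @param E internal energy (eV); may be a vector.
#' @param E0 critical (activation) energy of the pathway (eV), > 0.
#' @param v frequency factor (s^-1), > 0; loose transition states have large
#'   `v`, tight rearrangement-type ones small `v`.
#' @param N atom count of the dissociating ion (>= 3).
#' @return rate constant(s) in s^-1.
#' @examples
#' kasselRate(E = 3.2, E0 = 1.6, v = 1e12, N = 3)  # v * (1/2)^2
#' @export
kasselRate <- function(E, E0, v, N) {
  if (N < 3) stop("atom count N must be >= 3 (3N - 7 degrees of freedom)")
  stopifnot(E0 > 0, v > 0, all(E >= 0))
  out <- numeric(length(E))
  open <- E > E0
  out[open] <- v * ((E[open] - E0) / E[open])^(3 * N - 7)
  out
}

#' Construct a FragmentationNetwork
#'
#' @param precursor name of the root species.
#' @param pathways data.frame with columns `parent`, `product`, `E0` (eV) and
#'   `v` (s^-1) — or `log10v` in place of `v`.
#' @param atoms named integer vector of atom counts; species missing from it
#'   default to the precursor's atom count.
#' @param mass named integer vector of nominal masses per species; defaults
#'   to an arbitrary distinct assignment if omitted.
#' @return a [FragmentationNetwork-class].
#' @export
newFragmentationNetwork <- function(precursor, pathways, atoms, mass = NULL) {
  stopifnot(is.data.frame(pathways),
            all(c("parent", "product", "E0") %in% names(pathways)))
  v <- if ("v" %in% names(pathways)) pathways$v else 10^pathways$log10v
  species <- unique(c(precursor, pathways$parent, pathways$product))
  if (!precursor %in% names(atoms))
    stop("atom count for the precursor is required")
  fullAtoms <- stats::setNames(rep(as.integer(atoms[[precursor]]),
                                   length(species)), species)
  fullAtoms[names(atoms)] <- as.integer(atoms)
  if (is.null(mass)) {
    mass <- stats::setNames(as.integer(100 + seq_along(species)), species)
  } else {
    miss <- setdiff(species, names(mass))
    if (length(miss)) stop("nominal mass missing for species: ",
                           paste(miss, collapse = ", "))
    mass <- stats::setNames(as.integer(mass[species]), species)
  }
  new("FragmentationNetwork", precursor = precursor, species = species,
      atoms = fullAtoms[species], mass = mass,
      parent = as.character(pathways$parent),
      product = as.character(pathways$product),
      E0 = as.numeric(pathways$E0), v = as.numeric(v))
}

#' Read / write a fragmentation-network YAML config
#'
#' The config carries: `precursor`, `atoms` (species -> atom count),
#' optional `mass` (species -> nominal mass), and `pathways`, a list of
#' records with `parent`, `product`, `E0` (eV) and `log10v`.
#'
#' @param path YAML file path.
#' @return [readNetworkConfig()]: a [FragmentationNetwork-class];
#'   [writeNetworkConfig()]: `path`, invisibly.
#' @export
readNetworkConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pw <- do.call(rbind, lapply(cfg$pathways, function(p)
    data.frame(parent = p$parent, product = p$product,
               E0 = p$E0, log10v = p$log10v, stringsAsFactors = FALSE)))
  newFragmentationNetwork(
    precursor = cfg$precursor, pathways = pw,
    atoms = unlist(cfg$atoms),
    mass = if (!is.null(cfg$mass)) unlist(cfg$mass) else NULL)
}

#' @rdname readNetworkConfig
#' @param network a [FragmentationNetwork-class].
#' @export
writeNetworkConfig <- function(network, path) {
  cfg <- list(
    precursor = network@precursor,
    atoms = as.list(network@atoms),
    mass = as.list(network@mass),
    pathways = lapply(seq_along(network@parent), function(i)
      list(parent = network@parent[i], product = network@product[i],
           E0 = network@E0[i], log10v = log10(network@v[i]))))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

## Per-species available internal energy. With inheritExcess, a fragment
## inherits E - E0 of its formation step (max over incoming edges when a
## species has several parents); otherwise every species sees the full E.
.availableEnergy <- function(network, E, inheritExcess = FALSE) {
  sp <- network@species
  Eav <- stats::setNames(rep(E, length(sp)), sp)
  if (!inheritExcess) return(Eav)
  ord <- .topo_order(sp, network@parent, network@product)
  Eav[] <- -Inf
  Eav[network@precursor] <- E
  for (s in ord) {
    idx <- which(network@product == s)
    for (i in idx) {
      cand <- Eav[[network@parent[i]]] - network@E0[i]
      if (cand > Eav[[s]]) Eav[s] <- cand
    }
  }
  pmax(Eav, 0)
}

## Edge rates at internal energy E; exponent uses the parent's atom count.
.edgeRates <- function(network, E, inheritExcess = FALSE) {
  Eav <- .availableEnergy(network, E, inheritExcess)
  vapply(seq_along(network@parent), function(i) {
    p <- network@parent[i]
    kasselRate(Eav[[p]], network@E0[i], network@v[i], network@atoms[[p]])
  }, numeric(1))
}

## Closed-form solution of the first-order decay network as per-species
## sums of exponentials. Returns NULL when two cascade rates nearly
## coincide (catastrophic-cancellation guard); callers then fall back to
## numerical integration.
.fractionTerms <- function(network, rates) {
  sp <- network@species
  ord <- .topo_order(sp, network@parent, network@product)
  Ktot <- stats::setNames(numeric(length(sp)), sp)
  for (i in seq_along(network@parent))
    Ktot[network@parent[i]] <- Ktot[network@parent[i]] + rates[i]
  terms <- stats::setNames(vector("list", length(sp)), sp)
  terms[[network@precursor]] <- list(lambda = Ktot[[network@precursor]], coef = 1)
  addTerm <- function(tr, lambda, coef) {
    j <- which(tr$lambda == lambda)
    if (length(j)) tr$coef[j[1L]] <- tr$coef[j[1L]] + coef
    else { tr$lambda <- c(tr$lambda, lambda); tr$coef <- c(tr$coef, coef) }
    tr
  }
  for (s in ord) {
    if (s == network@precursor) next
    tr <- list(lambda = numeric(0), coef = numeric(0))
    Ks <- Ktot[[s]]
    for (i in which(network@product == s)) {
      ke <- rates[i]
      if (ke == 0) next
      ptr <- terms[[network@parent[i]]]
      for (j in seq_along(ptr$lambda)) {
        lam <- ptr$lambda[j]
        denom <- Ks - lam
        if (abs(denom) < 1e-9 * max(abs(Ks), abs(lam), 1))
          return(NULL)  # near-equal cascade rates: defer to the ODE path
        a <- ke * ptr$coef[j] / denom
        tr <- addTerm(tr, lam, a)
        tr <- addTerm(tr, Ks, -a)
      }
    }
    terms[[s]] <- tr
  }
  terms
}

.evalTerms <- function(terms, t) {
  m <- vapply(terms, function(tr) {
    if (is.null(tr) || !length(tr$lambda)) return(rep(0, length(t)))
    colSums(tr$coef * exp(-outer(tr$lambda, t)))
  }, numeric(length(t)))
  if (length(t) == 1L)
    m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(terms)))
  m
}

## Numerical integration of the same linear system (deSolve), used both as
## the near-degenerate fallback and as an independent oracle in tests.
.odeFractions <- function(network, rates, t) {
  sp <- network@species
  y0 <- stats::setNames(numeric(length(sp)), sp)
  y0[network@precursor] <- 1
  Ktot <- stats::setNames(numeric(length(sp)), sp)
  for (i in seq_along(network@parent))
    Ktot[network@parent[i]] <- Ktot[network@parent[i]] + rates[i]
  deriv <- function(time, y, parms) {
    dy <- -Ktot * y
    for (i in seq_along(network@parent))
      dy[network@product[i]] <- dy[network@product[i]] +
        rates[i] * y[[network@parent[i]]]
    list(dy)
  }
  tt <- sort(unique(c(0, t)))
  sol <- deSolve::ode(y = y0, times = tt, func = deriv, parms = NULL,
                      rtol = 1e-12, atol = 1e-14)
  out <- sol[match(t, tt), sp, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fractional species abundances at a given energy and time
#'
#' Solves the first-order kinetic system of the network analytically
#' (sums of exponentials over the cascade) with all pathway rates evaluated
#' at internal energy `E` via [kasselRate()]. Starting from a pure precursor
#' population (`[M+] = 1` at `t = 0`), the precursor decays as
#' `exp(-k_tot * t)` with `k_tot` the sum of its channel rates; each
#' competitive channel's terminal product approaches `k_X / k_tot` as
#' `t -> Inf`, and sequential chains follow the standard consecutive-decay
#' closed form. When two cascade rates nearly coincide the closed form is
#' numerically unstable and the solver falls back to adaptive ODE
#' integration.
#'
#' @param network a [FragmentationNetwork-class].
#' @param E internal energy (eV), scalar; if below every channel's `E0` the
#'   precursor fraction is 1.
#' @param t observation time (s), scalar >= 0.
#' @param inheritExcess logical; if TRUE a fragment's internal energy is the
#'   parent's energy minus the formation step's `E0` (energy partitioning),
#'   otherwise all species see the full `E`.
#' @return named numeric vector of species fractions summing to 1.
#' @export
speciesFractions <- function(network, E, t, inheritExcess = FALSE) {
  stopifnot(is(network, "FragmentationNetwork"),
            length(E) == 1L, length(t) == 1L, t >= 0, E >= 0)
  rates <- .edgeRates(network, E, inheritExcess)
  terms <- .fractionTerms(network, rates)
  fr <- if (is.null(terms)) .odeFractions(network, rates, t)[1L, ]
        else .evalTerms(terms, t)[1L, ]
  stats::setNames(as.numeric(fr), network@species)
}

#' Breakdown curve over a time or energy grid
#'
#' Fractional abundance of every species as a function of observation time
#' (at fixed internal energy) or of internal energy (at fixed time).
#'
#' @param network a [FragmentationNetwork-class].
#' @param mode `"time"` (grid of seconds, `fixed` = energy in eV) or
#'   `"energy"` (grid of eV, `fixed` = time in s).
#' @param fixed the held value.
#' @param grid strictly increasing axis values, length >= 2.
#' @param inheritExcess see [speciesFractions()].
#' @return a [BreakdownCurve-class].
#' @export
breakdownCurve <- function(network, mode = c("time", "energy"), fixed, grid,
                           inheritExcess = FALSE) {
  mode <- match.arg(mode)
  if (length(grid) < 2L) stop("grid must contain at least 2 points")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (mode == "time") {
    rates <- .edgeRates(network, fixed, inheritExcess)
    terms <- .fractionTerms(network, rates)
    fr <- if (is.null(terms)) .odeFractions(network, rates, grid)
          else .evalTerms(terms, grid)
    if (is.null(dim(fr))) fr <- matrix(fr, nrow = length(grid))
  } else {
    fr <- t(vapply(grid, function(E)
      speciesFractions(network, E, fixed, inheritExcess),
      numeric(length(network@species))))
  }
  colnames(fr) <- network@species
  fr <- pmin(pmax(fr, 0), 1)
  new("BreakdownCurve", mode = mode, fixed = as.numeric(fixed),
      axis = as.numeric(grid), fractions = fr)
}

#' Export a breakdown curve as CSV
#'
#' @param curve a [BreakdownCurve-class].
#' @param path output path. First column is the axis (named `time_s` or
#'   `energy_eV`), then one column per species.
#' @return `path`, invisibly.
#' @export
writeBreakdownCSV <- function(curve, path) {
  axisName <- if (curve@mode == "time") "time_s" else "energy_eV"
  df <- data.frame(curve@axis, curve@fractions, check.names = FALSE)
  names(df)[1L] <- axisName
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Linearity of fragment-fragment relationships under perturbation
#'
#' Scans a window of internal energy (or observation time) around a center
#' value and regresses every species' fractional abundance on the reference
#' species' abundance by ordinary least squares. Near-unity squared
#' correlations over such windows are what justify linear cross-instrument
#' extrapolation: modest changes in energy or time move all branching
#' fractions along approximately straight lines against one another.
#'
#' @param network a [FragmentationNetwork-class].
#' @param reference species whose abundance is the regressor.
#' @param mode `"energy"` or `"time"`: the perturbed axis.
#' @param center center of the perturbation window (eV or s).
#' @param halfWidthFrac half-width of the window as a fraction of `center`,
#'   in (0, 1); the default 0.15 mirrors a roughly one-third total swing.
#' @param k number of grid points (>= 3).
#' @param fixed held value of the other axis (time in s for an energy scan
#'   and vice versa).
#' @param inheritExcess see [speciesFractions()].
#' @return data.frame with one row per non-reference species: `species`,
#'   `slope`, `intercept`, `r.squared`, `degenerate` (TRUE when the species'
#'   abundance has zero variance over the window, in which case no
#'   regression is reported). Attributes `reference`, `mode`, `axis`.
#' @export
linearityScan <- function(network, reference, mode = c("energy", "time"),
                          center, halfWidthFrac = 0.15, k = 25, fixed,
                          inheritExcess = FALSE) {
  mode <- match.arg(mode)
  if (!reference %in% network@species)
    stop("reference species '", reference, "' not in network")
  if (halfWidthFrac <= 0 || halfWidthFrac >= 1)
    stop("halfWidthFrac must be in (0, 1)")
  if (k < 3) stop("k must be >= 3")
  grid <- seq(center * (1 - halfWidthFrac), center * (1 + halfWidthFrac),
              length.out = k)
  curve <- breakdownCurve(network, mode = mode, fixed = fixed, grid = grid,
                          inheritExcess = inheritExcess)
  fr <- curve@fractions
  x <- fr[, reference]
  if (stats::var(x) <= .Machine$double.eps * max(mean(x)^2, 1))
    stop("reference species abundance is constant over the window")
  others <- setdiff(network@species, reference)
  res <- lapply(others, function(s) {
    y <- fr[, s]
    if (stats::var(y) <= 1e-300)
      return(data.frame(species = s, slope = NA_real_, intercept = NA_real_,
                        r.squared = NA_real_, degenerate = TRUE))
    b <- stats::cov(x, y) / stats::var(x)
    a <- mean(y) - b * mean(x)
    r2 <- stats::cor(x, y)^2
    data.frame(species = s, slope = b, intercept = a, r.squared = r2,
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "mode") <- mode
  attr(out, "axis") <- grid
  out
}
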