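#' Construct a Spectrum from a peak list
#'
#' Fractional m/z values are binned to nominal mass by round-half-up; peaks
#' that collide in the same nominal bin have their abundances summed.
#'
#' @param mz numeric vector of m/z values (binned to integers).
#' @param abundance numeric vector of non-negative abundances.
#' @param id spectrum identifier.
#' @param label class tag: "known-positive", "known-negative" or "unlabeled".
#' @param source free-text laboratory/instrument tag.
#' @param normalized logical; set TRUE only if abundances are already scaled
#'   to base peak = 100.
#' @return a [Spectrum-class].
#' @examples
#' s <- newSpectrum(c(82, 182), c(500, 400), id = "ex1")
#' peaks(normalizeToBasePeak(s))
#' @export
newSpectrum <- function(mz, abundance, id, label = "unlabeled", source = "",
                        normalized = FALSE) {
  stopifnot(length(mz) == length(abundance))
  nominal <- floor(as.numeric(mz) + 0.5)  # round half-up, paper-style nominal mass
  ab <- vapply(split(as.numeric(abundance), nominal), sum, numeric(1))
  ord <- order(as.integer(names(ab)))
  ab <- ab[ord]
  new("Spectrum", id = as.character(id), label = label, source = source,
      peaks = ab, normalized = normalized)
}

#' Construct a SpectrumLibrary
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param compound compound name.
#' @return a [SpectrumLibrary-class].
#' @export
newSpectrumLibrary <- function(spectra, compound = NA_character_) {
  new("SpectrumLibrary", spectra = spectra, compound = as.character(compound))
}

#' Read a NIST MSP spectral library
#'
#' Parses the NIST MSP text dialect: records begin with `Name:`, carry a
#' `Num Peaks:` header, and list "mz intensity" pairs separated by
#' semicolons, whitespace or newlines. Optional `Comments:`/`MW:` style
#' headers are retained loosely (a `Lab:` or `Source:` header populates the
#' spectrum source; a `Label:` header the class tag). Raw intensities are
#' preserved; call [normalizeToBasePeak()] before modeling.
#'
#' @param path path to an MSP file.
#' @param compound compound name for the library (defaults to the first
#'   record's name).
#' @return a [SpectrumLibrary-class] with one spectrum per record, in file
#'   order.
#' @export
readMSP <- function(path, compound = NULL) {
  if (!file.exists(path)) stop("MSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!any(nzchar(lines))) stop("empty MSP file: ", path)

  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^Name[[:space:]]*:", lines[i], ignore.case = TRUE)) {
      i <- i + 1L
      next
    }
    name <- trimws(sub("^Name[[:space:]]*:", "", lines[i], ignore.case = TRUE))
    src <- ""
    label <- "unlabeled"
    numPeaks <- NA_integer_
    i <- i + 1L
    ## headers until Num Peaks:
    while (i <= n && !grepl("^Num[[:space:]]*Peaks[[:space:]]*:", lines[i],
                            ignore.case = TRUE)) {
      if (grepl("^Name[[:space:]]*:", lines[i], ignore.case = TRUE))
        stop("record '", name, "' has no 'Num Peaks:' header")
      if (grepl("^(Lab|Source)[[:space:]]*:", lines[i], ignore.case = TRUE))
        src <- trimws(sub("^[^:]+:", "", lines[i]))
      if (grepl("^Label[[:space:]]*:", lines[i], ignore.case = TRUE))
        label <- trimws(sub("^[^:]+:", "", lines[i]))
      i <- i + 1L
    }
    if (i > n) stop("record '", name, "' has no 'Num Peaks:' header")
    numPeaks <- as.integer(trimws(sub("^Num[[:space:]]*Peaks[[:space:]]*:", "",
                                      lines[i], ignore.case = TRUE)))
    i <- i + 1L
    ## peak lines until blank line or next Name:
    toks <- character(0)
    while (i <= n && nzchar(lines[i]) &&
           !grepl("^Name[[:space:]]*:", lines[i], ignore.case = TRUE)) {
      toks <- c(toks, lines[i])
      i <- i + 1L
    }
    pairs <- unlist(strsplit(paste(toks, collapse = " "), "[;\n]+"))
    pairs <- trimws(pairs)
    pairs <- pairs[nzchar(pairs)]
    nums <- suppressWarnings(as.numeric(unlist(strsplit(paste(pairs, collapse = " "),
                                                        "[[:space:],]+"))))
    nums <- nums[!is.na(nums)]
    if (length(nums) %% 2L != 0L)
      stop("record '", name, "': malformed peak list (odd token count)")
    mz <- nums[seq(1L, length(nums), by = 2L)]
    ab <- nums[seq(2L, length(nums), by = 2L)]
    if (length(mz) != numPeaks)
      stop("record '", name, "': declared Num Peaks (", numPeaks,
           ") does not match parsed peak count (", length(mz), ")")
    if (!label %in% c("known-positive", "known-negative", "unlabeled"))
      label <- "unlabeled"
    spectra[[length(spectra) + 1L]] <-
      newSpectrum(mz, ab, id = name, label = label, source = src)
  }
  if (!length(spectra)) stop("no MSP records found in ", path)
  if (is.null(compound)) compound <- spectra[[1L]]@id
  newSpectrumLibrary(spectra, compound = compound)
}

#' Write a SpectrumLibrary in NIST MSP format
#'
#' Emits the same dialect [readMSP()] reads (newline-separated "mz intensity"
#' pairs), so read -> write -> read round-trips peak lists exactly at the
#' printed precision.
#'
#' @param library a [SpectrumLibrary-class].
#' @param path output file path.
#' @param digits significant digits for intensities.
#' @return `path`, invisibly.
#' @export
writeMSP <- function(library, path, digits = 10) {
  stopifnot(is(library, "SpectrumLibrary"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in library@spectra) {
    cat("Name: ", s@id, "\n", sep = "", file = con)
    if (nzchar(s@source)) cat("Source: ", s@source, "\n", sep = "", file = con)
    if (s@label != "unlabeled") cat("Label: ", s@label, "\n", sep = "", file = con)
    cat("Num Peaks: ", length(s@peaks), "\n", sep = "", file = con)
    mz <- as.integer(names(s@peaks))
    for (j in seq_along(mz))
      cat(mz[j], " ", format(s@peaks[[j]], digits = digits), "\n",
          sep = "", file = con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' @rdname normalizeToBasePeak
#' @export
setMethod("normalizeToBasePeak", "Spectrum", function(object) {
  p <- object@peaks
  if (!length(p) || all(p == 0))
    stop("cannot normalize spectrum '", object@id,
         "': no peak with positive abundance")
  mx <- max(p)
  object@peaks <- p * (100 / mx)
  object@normalized <- TRUE
  validObject(object)
  object
})

#' @rdname normalizeToBasePeak
#' @export
setMethod("normalizeToBasePeak", "SpectrumLibrary", function(object) {
  object@spectra <- lapply(object@spectra, normalizeToBasePeak)
  object
})

#' Base peak of a spectrum
#'
#' The m/z of the most abundant peak; ties resolved to the lowest m/z.
#'
#' @param spectrum a [Spectrum-class].
#' @return integer nominal mass of the base peak.
#' @export
basePeak <- function(spectrum) {
  p <- spectrum@peaks
  if (!length(p)) stop("empty spectrum")
  mz <- as.integer(names(p))
  min(mz[p == max(p)])
}

#' Select the modeled ion panel
#'
#' Ranks ions by mean normalized abundance across the library and keeps the
#' top `n`, after guaranteeing any `forceInclude` members a slot (forced ions
#' displace the lowest-ranked unforced ions). Ties in mean abundance are
#' broken toward the lower m/z. The returned panel is ordered by decreasing
#' score, then increasing m/z.
#'
#' @param library a normalized [SpectrumLibrary-class].
#' @param n panel size (default 20).
#' @param forceInclude integer m/z values that must be in the panel even if
#'   not among the top `n` by abundance.
#' @return an [IonPanel-class].
#' @export
selectTopIons <- function(library, n = 20, forceInclude = integer(0)) {
  stopifnot(is(library, "SpectrumLibrary"))
  if (n < 2) stop("panel size n must be >= 2")
  if (!isNormalized(library))
    stop("library must be normalized before panel selection")
  mat <- .fullAbundanceMatrix(library)
  means <- colMeans(mat)
  mzs <- as.integer(colnames(mat))
  if (n > length(mzs))
    stop("requested panel size ", n, " exceeds the ", length(mzs),
         " distinct observed m/z values")
  forceInclude <- as.integer(forceInclude)
  missing <- setdiff(forceInclude, mzs)
  if (length(missing))
    stop("forced ion(s) absent from all spectra: m/z ",
         paste(missing, collapse = ", "))
  ord <- order(-means, mzs)          # score desc, then m/z asc
  ranked <- mzs[ord]
  forced <- intersect(ranked, forceInclude)
  if (length(forced) > n) stop("more forced ions than panel slots")
  unforced <- setdiff(ranked, forced)
  chosen <- c(forced, unforced[seq_len(n - length(forced))])
  sel <- means[as.character(chosen)]
  ord2 <- order(-sel, chosen)
  new("IonPanel", mz = as.integer(chosen[ord2]),
      score = unname(sel[ord2]))
}

## spectra x all-observed-mz matrix (internal)
.fullAbundanceMatrix <- function(library) {
  mzs <- sort(unique(unlist(lapply(library@spectra,
                                   function(s) as.integer(names(s@peaks))))))
  mat <- matrix(0, nrow = length(library@spectra), ncol = length(mzs),
                dimnames = list(spectrumIds(library), as.character(mzs)))
  for (i in seq_along(library@spectra)) {
    p <- library@spectra[[i]]@peaks
    mat[i, names(p)] <- p
  }
  mat
}

#' Build the spectra-by-ions abundance matrix
#'
#' Entry (i, j) is the normalized abundance of panel ion j in spectrum i;
#' a panel ion absent from a spectrum is recorded as 0 (not detected). Row
#' order follows the library; column order follows the panel.
#'
#' @param library a normalized [SpectrumLibrary-class].
#' @param panel an [IonPanel-class].
#' @return a numeric matrix with spectrum ids as rownames and panel m/z as
#'   colnames; all-zero panel columns are listed in
#'   `attr(, "emptyColumns")` and flagged with a warning.
#' @export
buildAbundanceMatrix <- function(library, panel) {
  stopifnot(is(library, "SpectrumLibrary"), is(panel, "IonPanel"))
  if (!length(panel@mz)) stop("empty ion panel")
  if (!isNormalized(library))
    stop("library must be normalized before building the abundance matrix")
  cols <- as.character(panel@mz)
  mat <- matrix(0, nrow = length(library@spectra), ncol = length(cols),
                dimnames = list(spectrumIds(library), cols))
  for (i in seq_along(library@spectra)) {
    p <- library@spectra[[i]]@peaks
    hit <- intersect(names(p), cols)
    mat[i, hit] <- p[hit]
  }
  empty <- cols[colSums(mat != 0) == 0L]
  if (length(empty)) {
    warning("panel ion(s) present in no spectrum: m/z ",
            paste(empty, collapse = ", "))
  }
  attr(mat, "emptyColumns") <- as.integer(empty)
  mat
}

#' Export an abundance matrix as CSV
#'
#' One row per spectrum id, one column per panel m/z.
#'
#' @param matrix an abundance matrix from [buildAbundanceMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAbundanceCSV <- function(matrix, path) {
  df <- data.frame(spectrum = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
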