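#' SignalTrack: a binned, per-locus feature signal
#'
#' One real value per genomic bin for a single chromatin feature in a single
#' cell type.  Values are fold-change over input chromatin (unitless) unless
#' stated otherwise (the GC track stores a fraction).  Bins flagged in
#' \code{mask} are unusable and carry no finiteness requirement.
#'
#' @slot bins [GRanges] the genome binning (with \code{arm} and
#'   \code{binIndex} metadata columns, as produced by [makeBins()]).
#' @slot values numeric, one value per bin.
#' @slot featureName single string, e.g. \code{"CTCF"}.
#' @slot cellType single string.
#' @slot mask logical per bin; \code{TRUE} = unusable.
#' @export
setClass("SignalTrack",
  representation(bins = "GRanges", values = "numeric",
                 featureName = "character", cellType = "character",
                 mask = "logical"))

setValidity("SignalTrack", function(object) {
  n <- length(object@bins)
  if (length(object@values) != n) return("length(values) != length(bins)")
  if (length(object@mask) != n) return("length(mask) != length(bins)")
  if (any(!is.finite(object@values[!object@mask])))
    return("unmasked values must be finite")
  TRUE
})

#' ContactMatrix: symmetric binned intrachromosomal Hi-C counts for one arm
#'
#' @slot matrix symmetric non-negative n x n matrix (diagonal conventionally 0).
#' @slot bins [GRanges] of the n bins of one chromosome arm.
#' @slot mask logical per bin; masked rows/columns are zeroed by correction.
#' @slot corrected logical flag: has [iceCorrect()] been applied.
#' @slot biases per-bin multiplicative bias estimates (NA before correction and
#'   at masked bins); \code{raw = corrected * outer(biases, biases)}.
#' @slot converged logical; FALSE if iterative correction hit max_iter.
#' @export
setClass("ContactMatrix",
  representation(matrix = "matrix", bins = "GRanges", mask = "logical",
                 corrected = "logical", biases = "numeric",
                 converged = "logical"))

setValidity("ContactMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (length(object@bins) != nrow(m)) return("bins do not match matrix")
  if (length(object@mask) != nrow(m)) return("mask does not match matrix")
  if (any(m < 0)) return("counts must be non-negative")
  if (!isSymmetric(unname(m), tol = 1e-8)) return("matrix must be symmetric")
  TRUE
})

#' Eigenvector: per-bin compartment score for one chromosome arm
#'
#' Leading eigenvector of the Pearson correlation of the observed/expected
#' contact map.  Oriented so that it correlates positively with the sign
#' anchor track (GC content by default), hence A-compartment bins score
#' \code{>= 0}.  Masked bins hold NA.
#'
#' @slot values numeric per bin, NA at masked bins; unit norm over unmasked.
#' @slot mask logical per bin.
#' @slot bins [GRanges].
#' @slot signAnchor name of the track used for sign orientation.
#' @slot eigenvalue the corresponding (largest) eigenvalue.
#' @export
setClass("Eigenvector",
  representation(values = "numeric", mask = "logical", bins = "GRanges",
                 signAnchor = "character", eigenvalue = "numeric"))

setValidity("Eigenvector", function(object) {
  if (length(object@values) != length(object@mask))
    return("values and mask lengths differ")
  if (any(!is.na(object@values[object@mask])))
    return("masked bins must carry NA")
  TRUE
})

#' BoundarySet: ordered boundary positions of one class on one arm
#'
#' A boundary between bins k-1 and k is recorded as k (0-based index of the
#' first bin of the new domain), so positions lie in 1..(nBins-1).
#'
#' @slot positions strictly increasing integer bin indices.
#' @slot btype \code{"TAD"} or \code{"compartment"}.
#' @slot resolution bin size in bp.
#' @slot nBins number of bins on the arm (needed by null models).
#' @export
setClass("BoundarySet",
  representation(positions = "integer", btype = "character",
                 resolution = "numeric", nBins = "integer"))

setValidity("BoundarySet", function(object) {
  p <- object@positions
  if (length(p) && (is.unsorted(p, strictly = TRUE)))
    return("positions must be strictly increasing")
  if (length(p) && (min(p) < 1L || max(p) > object@nBins - 1L))
    return("positions must lie within 1..(nBins-1)")
  if (!object@btype %in% c("TAD", "compartment"))
    return("btype must be 'TAD' or 'compartment'")
  TRUE
})

#' GaussianHMM: a hidden Markov model with Gaussian emissions
#'
#' @slot initial initial state distribution.
#' @slot transition row-stochastic transition matrix.
#' @slot means,sds per-state emission parameters (sd > 0).
#' @slot stateNames optional labels (e.g. A/B).
#' @slot logLik log-likelihood at convergence.
#' @slot converged logical.
#' @export
setClass("GaussianHMM",
  representation(initial = "numeric", transition = "matrix",
                 means = "numeric", sds = "numeric",
                 stateNames = "character", logLik = "numeric",
                 converged = "logical"))

setValidity("GaussianHMM", function(object) {
  k <- length(object@means)
  if (length(object@sds) != k || length(object@initial) != k)
    return("parameter lengths disagree")
  if (any(object@sds <= 0)) return("sds must be positive")
  if (nrow(object@transition) != k || ncol(object@transition) != k)
    return("transition must be k x k")
  if (any(abs(rowSums(object@transition) - 1) > 1e-6))
    return("transition rows must sum to 1")
  TRUE
})

## ---- accessors ----

#' @describeIn SignalTrack-class per-bin values
#' @param x object
#' @export
signalValues <- function(x) x@values

#' @describeIn SignalTrack-class feature name
#' @export
featureName <- function(x) x@featureName

#' @describeIn SignalTrack-class cell type
#' @export
cellType <- function(x) x@cellType

#' Per-bin mask of an object
#' @param x a SignalTrack, ContactMatrix or Eigenvector
#' @return logical vector, TRUE = unusable bin
#' @export
binMask <- function(x) x@mask

#' Bins of an object
#' @param x a SignalTrack, ContactMatrix, Eigenvector or GRanges
#' @return GRanges of bins
#' @export
binsOf <- function(x) if (is(x, "GRanges")) x else x@bins

#' @describeIn ContactMatrix-class the count matrix
#' @param x object
#' @export
contactCounts <- function(x) x@matrix

#' @describeIn ContactMatrix-class per-bin bias estimates (NA if uncorrected)
#' @export
biasEstimates <- function(x) x@biases

#' @describeIn ContactMatrix-class has iterative correction been applied
#' @export
isCorrected <- function(x) x@corrected

#' @describeIn Eigenvector-class per-bin compartment scores (NA at masked bins)
#' @param x object
#' @export
eigScores <- function(x) x@values

#' @describeIn BoundarySet-class boundary bin indices
#' @param x object
#' @export
boundaryPositions <- function(x) x@positions

#' @describeIn BoundarySet-class boundary class ("TAD" or "compartment")
#' @export
boundaryType <- function(x) x@btype

## ---- show methods ----

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack '%s' [%s]: %d bins (%d masked), mean %.3f\n",
              object@featureName, object@cellType, length(object@values),
              sum(object@mask),
              mean(object@values[!object@mask])))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %d x %d bins (%d masked), %s, total %.3g\n",
              nrow(object@matrix), ncol(object@matrix), sum(object@mask),
              if (object@corrected) "corrected" else "raw",
              sum(object@matrix)))
})

setMethod("show", "Eigenvector", function(object) {
  v <- object@values[!object@mask]
  cat(sprintf(
    "Eigenvector: %d bins (%d masked), eigenvalue %.3f, %d A / %d B (anchor: %s)\n",
    length(object@values), sum(object@mask), object@eigenvalue,
    sum(v >= 0), sum(v < 0), object@signAnchor))
})

setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet (%s): %d boundaries over %d bins @ %g bp\n",
              object@btype, length(object@positions), object@nBins,
              object@resolution))
})

setMethod("show", "GaussianHMM", function(object) {
  cat(sprintf("GaussianHMM with %d states (%s)\n", length(object@means),
              paste(object@stateNames, collapse = "/")))
  cat("  means:", signif(object@means, 4), "\n")
  cat("  sds:  ", signif(object@sds, 4), "\n")
  cat("  self-transitions:", signif(diag(object@transition), 4), "\n")
})

## ---- constructors (internal) ----

newSignalTrack <- function(bins, values, featureName, cellType = "NA",
                           mask = NULL) {
  if (is.null(mask)) mask <- !is.finite(values)
  new("SignalTrack", bins = bins, values = as.numeric(values),
      featureName = featureName, cellType = cellType, mask = mask)
}

newContactMatrix <- function(m, bins, mask = NULL, corrected = FALSE,
                             biases = NULL, converged = TRUE) {
  n <- nrow(m)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (is.null(biases)) biases <- rep(NA_real_, n)
  new("ContactMatrix", matrix = m, bins = bins, mask = mask,
      corrected = corrected, biases = biases, converged = converged)
}

#' Construct a BoundarySet
#'
#' @param positions boundary bin indices (boundary between bins k-1 and k
#'   recorded as k); coerced to sorted integers
#' @param btype "TAD" or "compartment"
#' @param resolution bin size in bp
#' @param nBins number of bins on the arm
#' @return [BoundarySet-class]
#' @export
boundarySet <- function(positions, btype = c("TAD", "compartment"),
                        resolution, nBins) {
  btype <- match.arg(btype)
  new("BoundarySet", positions = as.integer(sort(positions)), btype = btype,
      resolution = as.numeric(resolution), nBins = as.integer(nBins))
}

newBoundarySet <- function(positions, btype, resolution, nBins) {
  new("BoundarySet", positions = as.integer(sort(positions)), btype = btype,
      resolution = as.numeric(resolution), nBins = as.integer(nBins))
}
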