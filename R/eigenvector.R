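#' Expected contact profile by genomic separation
#'
#' Arithmetic mean contact at each separation d = 1..n-1 over unmasked bin
#' pairs.  Separations with fewer than 3 unmasked pairs inherit the nearest
#' smaller separation's value.
#'
#' @param cm [ContactMatrix-class]
#' @return numeric vector of length n-1, expected value at separations 1..n-1
#' @export
expectedProfile <- function(cm) {
  n <- nrow(cm@matrix)
  keep <- !cm@mask
  vals <- numeric(n - 1)
  counts <- integer(n - 1)
  for (d in seq_len(n - 1)) {
    i <- seq_len(n - d)
    ok <- keep[i] & keep[i + d]
    counts[d] <- sum(ok)
    vals[d] <- if (counts[d]) mean(cm@matrix[cbind(i[ok], i[ok] + d)]) else NA_real_
  }
  for (d in seq_len(n - 1))
    if (counts[d] < 3 && d > 1) { vals[d] <- vals[d - 1]; counts[d] <- counts[d - 1] }
  vals
}

#' Observed/expected transformation of a contact map
#'
#' Divides each entry by the expected contact at its separation (computed
#' from the same matrix).  Entries at separations with zero expected value,
#' and masked rows/columns, are set to NA.
#'
#' @param cm [ContactMatrix-class] (typically ICE-corrected)
#' @return list with `oe` (n x n matrix, NA where undefined) and `expected`
#'   (the [expectedProfile()])
#' @export
observedOverExpected <- function(cm) {
  n <- nrow(cm@matrix)
  expd <- expectedProfile(cm)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(NA_real_, n, n)
  off <- D > 0
  E[off] <- expd[D[off]]
  oe <- cm@matrix / E
  oe[!is.finite(oe)] <- NA_real_
  oe[cm@mask, ] <- NA_real_
  oe[, cm@mask] <- NA_real_
  diag(oe) <- NA_real_
  list(oe = oe, expected = expd)
}

#' Compartment eigenvector of one chromosome arm
#'
#' The canonical compartment recipe: Pearson correlation matrix of the
#' unmasked observed/expected columns, leading eigenvector (largest
#' eigenvalue) of the symmetric eigendecomposition, unit norm, sign oriented
#' so that its correlation with the anchor track (GC content by default) is
#' non-negative.  Masked bins are reinserted as NA.
#'
#' @param oe output of [observedOverExpected()] or the O/E matrix itself
#' @param signAnchor [SignalTrack-class] used for orientation (A = high
#'   anchor values); NULL leaves the arbitrary eigendecomposition sign.
#' @param cm the [ContactMatrix-class] the O/E came from (for bins + mask);
#'   required when `oe` is a bare matrix.
#' @return [Eigenvector-class]
#' @export
compartmentEigenvector <- function(oe, signAnchor = NULL, cm = NULL) {
  if (is.list(oe)) oe <- oe$oe
  n <- nrow(oe)
  mask <- apply(oe, 1, function(r) all(is.na(r)))
  keep <- which(!mask)
  if (length(keep) < 10) stop("need at least 10 unmasked bins")
  sub <- oe[keep, keep, drop = FALSE]
  ## the diagonal (and any expected-0 separation) is NA by construction;
  ## set those entries to the O/E-neutral value 1 so the dense correlation
  ## can be used (pairwise-complete correlation is quadratically slower and
  ## changes nothing material: the diagonal is a single entry per column)
  sub[is.na(sub)] <- 1
  C <- suppressWarnings(stats::cor(sub))
  if (any(!is.finite(C)))
    stop("degenerate correlation matrix (constant or empty columns)")
  ed <- eigen(C, symmetric = TRUE)
  v <- ed$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  anchorName <- "none"
  if (!is.null(signAnchor)) {
    anchorName <- signAnchor@featureName
    av <- signAnchor@values[keep]
    pcc <- suppressWarnings(stats::cor(v, av))
    if (is.finite(pcc) && pcc < 0) v <- -v
  }
  values <- rep(NA_real_, n)
  values[keep] <- v
  bins <- if (!is.null(cm)) cm@bins else
    if (!is.null(signAnchor)) signAnchor@bins else GRanges()
  if (length(bins) != n) bins <- GRanges(rep("unknown", n), IRanges(seq_len(n), width = 1))
  new("Eigenvector", values = values, mask = mask, bins = bins,
      signAnchor = anchorName, eigenvalue = ed$values[1])
}

#' Threshold an eigenvector into A/B compartment calls
#'
#' A wherever the eigenvector is >= 0 (including exactly 0), B where < 0;
#' masked bins get NA.
#'
#' @param eig [Eigenvector-class]
#' @return character vector of "A"/"B" (NA at masked bins)
#' @export
callCompartments <- function(eig) {
  ifelse(is.na(eig@values), NA_character_, ifelse(eig@values >= 0, "A", "B"))
}

#' Run the full per-arm compartment pipeline
#'
#' Mask low-coverage bins, ICE-correct, O/E, correlation eigenvector,
#' A/B calls.
#'
#' @param cm raw [ContactMatrix-class]
#' @param signAnchor [SignalTrack-class] over the same bins (GC by default
#'   in practice)
#' @param maskFrac passed to [maskLowCoverage()]
#' @param tol,maxIter passed to [iceCorrect()]
#' @return list: `corrected`, `oe`, `eig`, `calls`
#' @export
compartmentPipeline <- function(cm, signAnchor = NULL, maskFrac = 0.02,
                                tol = 1e-5, maxIter = 200) {
  cm <- maskLowCoverage(cm, maskFrac)
  corr <- iceCorrect(cm, tol = tol, maxIter = maxIter)
  oe <- observedOverExpected(corr)
  eig <- compartmentEigenvector(oe, signAnchor = signAnchor, cm = corr)
  list(corrected = corr, oe = oe, eig = eig, calls = callCompartments(eig))
}
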