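#' Profile scheme around a boundary
#'
#' `nBins = 2*flankBins + 1` odd columns, the centre column being the
#' boundary bin (the first bin of the downstream domain).  Presets:
#' [tadScheme()] = 25 columns of 40 kb (covering ~ +/- 500 kb);
#' [compartmentScheme()] = 31 columns of 100 kb (~ +/- 1.5 Mb).
#'
#' @param flankBins bins on each side of the centre
#' @param bin profile bin width in bp
#' @return a `profileScheme` list with `flankBins`, `bin`, `nBins`
#' @export
profileScheme <- function(flankBins, bin) {
  stopifnot(flankBins >= 1, bin > 0)
  structure(list(flankBins = as.integer(flankBins), bin = bin,
                 nBins = 2L * as.integer(flankBins) + 1L),
            class = "profileScheme")
}

#' @rdname profileScheme
#' @export
tadScheme <- function() profileScheme(12, 4e4)

#' @rdname profileScheme
#' @export
compartmentScheme <- function() profileScheme(15, 1e5)

#' Build a feature-signal profile around boundaries
#'
#' For each boundary whose full flanks lie inside the arm, the track values
#' are averaged into the scheme's bins centred on the boundary bin.
#' Boundaries too close to the arm ends are dropped and counted.  The track
#' resolution must divide the scheme bin size.
#'
#' @param boundaries [BoundarySet-class]
#' @param track [SignalTrack-class] over the arm's bins, at a resolution
#'   <= `scheme$bin`
#' @param scheme [profileScheme()]
#' @return a `boundaryProfile` list: `matrix` (boundaries x scheme bins),
#'   `mean`, `se` (per column), `featureName`, `scheme`, `nDropped`
#' @export
buildProfile <- function(boundaries, track, scheme) {
  res <- binSize(track@bins)
  if (res > scheme$bin) stop("track resolution must be <= scheme bin size")
  r <- scheme$bin / res
  if (abs(r - round(r)) > 1e-8)
    stop("scheme bin size must be a multiple of the track resolution")
  r <- as.integer(round(r))
  n <- length(track@values)
  f <- scheme$flankBins
  rows <- list(); used <- 0L; dropped <- 0L
  for (k in boundaries@positions) {
    centre <- k + 1L   # R index of the first bin of the new domain
    lo <- centre - (f * r) - (r - 1L) %/% 2L
    hi <- lo + scheme$nBins * r - 1L
    if (lo < 1 || hi > n) { dropped <- dropped + 1L; next }
    vals <- track@values[lo:hi]
    prof <- colMeans(matrix(vals, nrow = r))
    used <- used + 1L
    rows[[used]] <- prof
  }
  if (!used) stop("zero usable boundaries (all flanks truncated)")
  m <- do.call(rbind, rows)
  colnames(m) <- as.character(seq_len(scheme$nBins) - 1L - f)
  structure(list(matrix = m, mean = colMeans(m),
                 se = apply(m, 2, stats::sd) / sqrt(nrow(m)),
                 featureName = track@featureName, scheme = scheme,
                 nDropped = dropped),
            class = "boundaryProfile")
}

#' Mann-Whitney p-value with an exact small-sample path
#'
#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) p-value: exact distribution
#' when both groups have <= 50 values and no ties, otherwise the normal
#' approximation with tie correction (and no continuity correction, so the
#' statistic is a pure rank functional).
#'
#' @param x,y numeric samples
#' @param exact force (TRUE/FALSE) or auto-select (NA, default) the exact path
#' @return list `p` and `U` (the Mann-Whitney U for the first sample)
#' @export
mannWhitney <- function(x, y, exact = NA) {
  if (all(c(x, y) == c(x, y)[1])) return(list(p = 1, U = length(x) * length(y) / 2))
  if (is.na(exact))
    exact <- length(x) <= 50 && length(y) <= 50 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(p = wt$p.value, U = unname(wt$statistic))
}

#' Test feature enrichment/depletion at boundaries
#'
#' Compares the boundary (centre) bin values with the ten outermost bins of
#' the window (five from either side) by a two-tailed Mann-Whitney test
#' (normal approximation with tie correction).  By default the peripheral
#' values are pooled across boundaries; `peripheral = "perBoundary"`
#' summarises them to one mean per boundary first.  Significance is
#' Bonferroni-controlled at `alpha` across `nFeaturesTested` features.
#'
#' @param profile [buildProfile()] output (>= 10 boundaries)
#' @param nFeaturesTested number of features in the testing family
#' @param alpha family-wise level (default 0.01)
#' @param nPeripheral outermost bins per side used as the peripheral sample
#' @param peripheral "pooled" (default) or "perBoundary"
#' @return an `enrichmentResult` list: `featureName`, `pRaw`, `significant`,
#'   `direction` ("enriched"/"depleted"), `effect` (absolute mean
#'   difference), `nBoundaries`
#' @export
testEnrichment <- function(profile, nFeaturesTested = 1, alpha = 0.01,
                           nPeripheral = 5, peripheral = c("pooled", "perBoundary")) {
  peripheral <- match.arg(peripheral)
  m <- profile$matrix
  if (nrow(m) < 10) stop("need at least 10 usable boundaries")
  nc <- ncol(m)
  centre <- m[, profile$scheme$flankBins + 1L]
  periCols <- c(seq_len(nPeripheral), (nc - nPeripheral + 1L):nc)
  peri <- if (peripheral == "pooled") as.numeric(m[, periCols])
          else rowMeans(m[, periCols])
  mw <- mannWhitney(centre, peri, exact = FALSE)
  diffMeans <- mean(centre) - mean(peri)
  structure(list(featureName = profile$featureName, pRaw = mw$p,
                 significant = mw$p < alpha / nFeaturesTested,
                 direction = if (diffMeans >= 0) "enriched" else "depleted",
                 effect = abs(diffMeans), nBoundaries = nrow(m)),
            class = "enrichmentResult")
}

#' Partition boundaries by architectural-protein peak occupancy
#'
#' A boundary carries feature a (resp. b) if any a (b) peak overlaps its
#' boundary bin extended by `window` bp on each side.  Class "both"
#' additionally requires an a peak and a b peak that mutually overlap;
#' boundaries where both are present but no pair overlaps are reported
#' separately as "both_non_overlapping".  The partition over
#' \{a_only, b_only, both, both_non_overlapping, neither\} is exhaustive
#' and disjoint.
#'
#' @param boundaries [BoundarySet-class]
#' @param bins GRanges of the arm's bins (index order)
#' @param peaksA,peaksB GRanges of peak intervals
#' @param window bp added each side of the boundary bin (default 0: the
#'   boundary bin itself)
#' @return factor per boundary with the five levels above
#' @export
classifyBoundariesByPeaks <- function(boundaries, bins, peaksA, peaksB,
                                      window = 0) {
  lv <- c("a_only", "b_only", "both", "both_non_overlapping", "neither")
  out <- character(length(boundaries@positions))
  for (i in seq_along(boundaries@positions)) {
    k <- boundaries@positions[i]
    bb <- bins[k + 1L]
    win <- GRanges(seqnames(bb),
                   IRanges(max(1, start(bb) - window), end(bb) + window))
    aHit <- subsetByOverlaps(peaksA, win)
    bHit <- subsetByOverlaps(peaksB, win)
    hasA <- length(aHit) > 0; hasB <- length(bHit) > 0
    out[i] <- if (hasA && hasB) {
      if (any(overlapsAny(aHit, bHit))) "both" else "both_non_overlapping"
    } else if (hasA) "a_only" else if (hasB) "b_only" else "neither"
  }
  factor(out, levels = lv)
}

#' Enrichment tests per boundary subset
#'
#' Applies [buildProfile()] + [testEnrichment()] for every feature track
#' within each boundary subset, Bonferroni-corrected across features within
#' the subset.  Subsets with fewer than 10 usable boundaries are skipped.
#'
#' @param partition factor from [classifyBoundariesByPeaks()]
#' @param boundaries the [BoundarySet-class] the partition refers to
#' @param tracks list of [SignalTrack-class]
#' @param scheme [profileScheme()]
#' @param alpha family-wise level
#' @return data.frame: subset, feature, pRaw, significant, direction,
#'   effect, nBoundaries
#' @export
subsetEnrichment <- function(partition, boundaries, tracks, scheme,
                             alpha = 0.01) {
  res <- list()
  for (cls in levels(partition)) {
    pos <- boundaries@positions[partition == cls]
    if (length(pos) < 10) next
    bs <- newBoundarySet(pos, boundaries@btype, boundaries@resolution,
                         boundaries@nBins)
    for (tr in tracks) {
      er <- tryCatch(
        testEnrichment(buildProfile(bs, tr, scheme),
                       nFeaturesTested = length(tracks), alpha = alpha),
        error = function(e) NULL)
      if (is.null(er)) next
      res[[length(res) + 1]] <- data.frame(
        subset = cls, feature = er$featureName, pRaw = er$pRaw,
        significant = er$significant, direction = er$direction,
        effect = er$effect, nBoundaries = er$nBoundaries)
    }
  }
  if (!length(res)) return(data.frame())
  do.call(rbind, res)
}
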