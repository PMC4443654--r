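#' Mean feature signal per TAD
#'
#' TAD spans partition the arm between consecutive boundaries (and the arm
#' ends); each track is averaged over the span's bins, weighted by bin
#' width (only the last bin of an arm can differ in width).
#'
#' @param tads [BoundarySet-class] (btype "TAD") on one arm
#' @param tracks list of [SignalTrack-class] over the arm's bins
#' @return data.frame: tad, startBin, endBin (1-based inclusive), nBins,
#'   one column per feature
#' @export
summarizeTads <- function(tads, tracks) {
  n <- tads@nBins
  bp <- tads@positions
  starts <- c(1L, bp + 1L)
  ends <- c(bp, n)
  w <- width(binsOf(tracks[[1]]))
  out <- data.frame(tad = seq_along(starts), startBin = starts,
                    endBin = ends, nBins = ends - starts + 1L)
  for (tr in tracks) {
    v <- signalValues(tr)
    out[[featureName(tr)]] <- vapply(seq_along(starts), function(i) {
      idx <- starts[i]:ends[i]
      sum(v[idx] * w[idx]) / sum(w[idx])
    }, 0)
  }
  out
}

#' Cluster TADs into active / null / PcG classes
#'
#' Features are standardised (z-scores across TADs) and clustered by
#' k-means (k = 3, 25 restarts, fixed seed).  Clusters are mapped to
#' classes by which signature feature attains the highest standardised
#' cluster-centre value: active <-> DNase hypersensitivity, null (repressed
#' heterochromatin) <-> H3K9me3, PcG (polycomb) <-> H3K27me3.  The mapping
#' must be a bijection, otherwise an error with diagnostics is raised.
#'
#' @param summary [summarizeTads()] output (>= 3k TADs)
#' @param signatures named character: class -> feature column
#' @param k number of clusters (3)
#' @param seed RNG seed for the k-means restarts
#' @param nstart k-means restarts
#' @return list: `labels` (factor per TAD), `mapping` (cluster -> class),
#'   `centers` (standardised), `kmeans` (the stats::kmeans fit)
#' @export
clusterTads <- function(summary,
                        signatures = c(active = "DNase", null = "H3K9me3",
                                       PcG = "H3K27me3"),
                        k = 3, seed = 1, nstart = 25) {
  featCols <- setdiff(colnames(summary), c("tad", "startBin", "endBin", "nBins"))
  if (!all(signatures %in% featCols))
    stop("signature features missing from the summary: ",
         paste(setdiff(signatures, featCols), collapse = ", "))
  x <- scale(as.matrix(summary[, featCols, drop = FALSE]))
  if (nrow(x) < 3 * k) stop("need at least ", 3 * k, " TADs")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = nstart)
  sigCenters <- km$centers[, signatures, drop = FALSE]
  best <- apply(sigCenters, 1, which.max)
  if (anyDuplicated(best)) {
    print(sigCenters)
    stop("cluster-to-class mapping is not a bijection: ",
         "one signature feature is maximal in two cluster centres")
  }
  mapping <- stats::setNames(names(signatures)[best], seq_len(k))
  labels <- factor(mapping[km$cluster], levels = names(signatures))
  list(labels = labels, mapping = mapping, centers = km$centers, kmeans = km)
}

#' Cross-tabulate TAD classes against A/B compartments
#'
#' Each TAD is assigned to compartment A or B by the majority of its bins'
#' calls (ties go to A and are counted), then counts and row proportions of
#' classes within each compartment are reported.
#'
#' @param labels factor per TAD from [clusterTads()]
#' @param summary [summarizeTads()] output (for the TAD spans)
#' @param calls per-bin "A"/"B" calls on the same arm
#' @return list: `table` (2 x k counts, rows A/B), `proportions` (row-wise),
#'   `tadCompartment` (per TAD), `nTies`
#' @export
compartmentComposition <- function(labels, summary, calls) {
  nT <- nrow(summary)
  comp <- character(nT); ties <- 0L
  for (i in seq_len(nT)) {
    cc <- calls[summary$startBin[i]:summary$endBin[i]]
    nA <- sum(cc == "A", na.rm = TRUE); nB <- sum(cc == "B", na.rm = TRUE)
    if (nA == nB) ties <- ties + 1L
    comp[i] <- if (nA >= nB) "A" else "B"
  }
  tab <- table(compartment = factor(comp, levels = c("A", "B")),
               class = labels)
  list(table = tab, proportions = prop.table(tab, 1),
       tadCompartment = comp, nTies = ties)
}
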