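#' Per-bin structural variability across cell types (MAD)
#'
#' Median absolute deviation of the per-cell-type eigenvector values at each
#' bin (raw MAD, no consistency constant), computed over bins unmasked in at
#' least 3 cell types, then ranked and trisected into low/mid/high tertiles
#' (sizes differing by at most 1).
#'
#' @param eigs list of >= 3 [Eigenvector-class], same bins
#' @return data.frame: bin (1-based index), mad, tertile
#'   (factor low/mid/high)
#' @export
computeMad <- function(eigs) {
  stopifnot(length(eigs) >= 3)
  vals <- do.call(cbind, lapply(eigs, eigScores))
  nOk <- rowSums(!is.na(vals))
  keep <- which(nOk >= 3)
  mads <- apply(vals[keep, , drop = FALSE], 1, function(x)
    stats::mad(x[!is.na(x)], constant = 1))
  ord <- order(mads)
  ter <- character(length(keep))
  third <- length(keep) / 3
  ter[ord] <- rep(c("low", "mid", "high"),
                  c(ceiling(third), round(third),
                    length(keep) - ceiling(third) - round(third)))
  data.frame(bin = keep, mad = mads,
             tertile = factor(ter, levels = c("low", "mid", "high")))
}

#' Identify altered-compartment regions
#'
#' Bins called A in exactly one cell type and B in all others occupy an
#' altered open compartment in that cell type; the converse (B in exactly
#' one) is altered closed.  All-equal bins are class "none".  Bins not
#' called in every cell type are skipped.
#'
#' @param calls list over cell types of [callCompartments()] outputs
#'   (named; names become the cellType labels)
#' @return data.frame: bin, cellType, direction ("open"/"closed")
#' @export
findAlteredRegions <- function(calls) {
  m <- do.call(cbind, calls)
  if (is.null(colnames(m))) colnames(m) <- paste0("CT", seq_len(ncol(m)))
  k <- ncol(m)
  called <- rowSums(is.na(m)) == 0
  nA <- rowSums(m == "A")
  openRows <- which(called & nA == 1 & k >= 3)
  closedRows <- which(called & nA == k - 1 & k >= 3)
  minorityCt <- function(rows, state)
    colnames(m)[apply(m[rows, , drop = FALSE] == state, 1, which)]
  out <- rbind(
    if (length(openRows)) data.frame(bin = openRows,
                                     cellType = minorityCt(openRows, "A"),
                                     direction = "open"),
    if (length(closedRows)) data.frame(bin = closedRows,
                                       cellType = minorityCt(closedRows, "B"),
                                       direction = "closed"))
  if (is.null(out))
    return(data.frame(bin = integer(0), cellType = character(0),
                      direction = character(0)))
  out[order(out$bin), , drop = FALSE]
}

#' Shared/specific annotation counts in altered vs unaltered regions
#'
#' An annotation is shared if any same-label annotation of another cell
#' type overlaps it by >= 1 bp, else specific to its cell type.  Counts are
#' tallied per region class: "open" counts the active cell type's
#' annotations in its altered-open bins; "closed" likewise; "none" counts
#' every cell type's annotations over unaltered bins.  The enrichment ratio
#' compares per-(bin, cell type) specific densities, open vs none, with a
#' bootstrap CI over regions.
#'
#' @param regions [findAlteredRegions()] output
#' @param annotations GRanges with `name` (label) and `cellType` columns
#' @param bins GRanges binning
#' @param label annotation label to count (default "enhancer")
#' @param cellTypes cell type names (default: those present in annotations)
#' @param nBoot bootstrap replicates for the ratio CI
#' @param seed RNG seed for the bootstrap
#' @return list: `counts` (data.frame class x specific/shared), `ratio`,
#'   `ci` (2-vector), `densities`
#' @export
countAnnotations <- function(regions, annotations, bins, label = "enhancer",
                             cellTypes = NULL, nBoot = 1000, seed = 1) {
  ann <- annotations[annotations$name == label]
  if (is.null(cellTypes)) cellTypes <- sort(unique(ann$cellType))
  ## shared = overlapped by a same-label record of ANY other cell type
  shared <- logical(length(ann))
  for (ct in cellTypes) {
    sel <- ann$cellType == ct
    other <- ann[ann$cellType != ct]
    if (length(other)) shared[sel] <- overlapsAny(ann[sel], other)
  }
  perBinCt <- function(binIdx, ct) {
    hits <- findOverlaps(ann[ann$cellType == ct], bins[binIdx])
    i <- which(ann$cellType == ct)[S4Vectors::queryHits(hits)]
    c(specific = sum(!shared[i]), shared = sum(shared[i]))
  }
  altBins <- regions$bin
  classes <- list(open = regions[regions$direction == "open", ],
                  closed = regions[regions$direction == "closed", ])
  counts <- data.frame()
  specOpen <- c(); nOpen <- 0
  for (cls in names(classes)) {
    r <- classes[[cls]]
    tot <- c(specific = 0, shared = 0)
    dens <- numeric(nrow(r))
    if (nrow(r)) for (j in seq_len(nrow(r))) {
      cc <- perBinCt(r$bin[j], r$cellType[j])
      tot <- tot + cc
      dens[j] <- cc["specific"]
    }
    counts <- rbind(counts, data.frame(class = cls, specific = tot["specific"],
                                       shared = tot["shared"],
                                       nRegions = nrow(r)))
    if (cls == "open") { specOpen <- dens; nOpen <- nrow(r) }
  }
  noneBins <- setdiff(seq_along(bins), altBins)
  noneDens <- numeric(0)
  tot <- c(specific = 0, shared = 0)
  for (ct in cellTypes) {
    hits <- findOverlaps(ann[ann$cellType == ct], bins[noneBins])
    i <- which(ann$cellType == ct)[S4Vectors::queryHits(hits)]
    perBin <- table(factor(S4Vectors::subjectHits(hits),
                           levels = seq_along(noneBins)))
    specPerBin <- tapply(!shared[i],
                         factor(S4Vectors::subjectHits(hits),
                                levels = seq_along(noneBins)), sum)
    specPerBin[is.na(specPerBin)] <- 0
    noneDens <- c(noneDens, as.numeric(specPerBin))
    tot <- tot + c(specific = sum(!shared[i]), shared = sum(shared[i]))
  }
  counts <- rbind(counts, data.frame(class = "none", specific = tot["specific"],
                                     shared = tot["shared"],
                                     nRegions = length(noneBins)))
  rownames(counts) <- NULL
  dOpen <- mean(specOpen); dNone <- mean(noneDens)
  ratio <- dOpen / dNone
  ci <- c(NA_real_, NA_real_)
  if (nOpen > 1 && dNone > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(nBoot), function(r) {
      mean(sample(specOpen, nOpen, replace = TRUE)) /
        mean(sample(noneDens, length(noneDens), replace = TRUE))
    }, 0)
    ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
  }
  list(counts = counts, ratio = ratio, ci = unname(ci),
       densities = list(open = dOpen, none = dNone))
}

#' Rank altered-open regions by specific-enhancer density
#'
#' Counts the active cell type's cell-type-specific annotations per
#' altered-open region and sorts in descending order, ties broken by
#' genomic (bin) order.
#'
#' @param regions [findAlteredRegions()] output (open rows used)
#' @param annotations GRanges with `name`, `cellType`
#' @param bins GRanges binning
#' @param label annotation label (default "enhancer")
#' @return data.frame: bin, cellType, count, rank, sorted by rank
#' @export
rankRegionsByEnhancers <- function(regions, annotations, bins,
                                   label = "enhancer") {
  open <- regions[regions$direction == "open", , drop = FALSE]
  ann <- annotations[annotations$name == label]
  shared <- logical(length(ann))
  for (ct in unique(ann$cellType)) {
    sel <- ann$cellType == ct
    other <- ann[ann$cellType != ct]
    if (length(other)) shared[sel] <- overlapsAny(ann[sel], other)
  }
  counts <- vapply(seq_len(nrow(open)), function(j) {
    sel <- ann$cellType == open$cellType[j] & !shared
    sum(overlapsAny(ann[sel], bins[open$bin[j]]))
  }, 0L)
  ord <- order(-counts, open$bin)
  out <- open[ord, , drop = FALSE]
  out$count <- counts[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' A-compartment contact fraction of a region
#'
#' For each region bin, the fraction of its (corrected) intrachromosomal
#' contacts at separation >= `minSeparation` bins landing in A-labelled
#' bins, computed in each cell type.  The region's own bin is excluded by
#' the separation cutoff; masked and uncalled bins are excluded from both
#' numerator and denominator.
#'
#' @param regionBins integer bin indices (1-based, within the arm)
#' @param contacts list over cell types of [ContactMatrix-class] for the arm
#' @param calls list over cell types of per-bin "A"/"B" calls for the arm
#' @param minSeparation minimum separation in bins (default 2, focusing on
#'   longer-range contacts)
#' @return matrix regions x cell types of fractions in \[0,1\] (NA where the
#'   region is masked)
#' @export
aContactFraction <- function(regionBins, contacts, calls, minSeparation = 2) {
  nCt <- length(contacts)
  out <- matrix(NA_real_, length(regionBins), nCt)
  rownames(out) <- as.character(regionBins)
  colnames(out) <- names(contacts)
  for (ct in seq_len(nCt)) {
    m <- contacts[[ct]]@matrix
    mask <- contacts[[ct]]@mask
    lab <- calls[[ct]]
    n <- nrow(m)
    for (j in seq_along(regionBins)) {
      r <- regionBins[j]
      if (mask[r]) next
      idx <- which(abs(seq_len(n) - r) >= minSeparation & !mask & !is.na(lab))
      tot <- sum(m[r, idx])
      if (tot > 0) out[j, ct] <- sum(m[r, idx[lab[idx] == "A"]]) / tot
    }
  }
  out
}
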