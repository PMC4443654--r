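#' Tile a genome into uniform bins, split at centromeres into arms
#'
#' Each chromosome is split at its centromere midpoint into p and q arms when
#' a centromere is supplied, otherwise kept as one "whole" arm.  Bins tile
#' each arm from its start; the last bin of an arm may be truncated.  Bin
#' indices are dense from 0 within each arm.  Coordinates are 0-based
#' half-open internally; the returned GRanges uses the usual 1-based closed
#' convention with `start0`/`end0` recoverable as `start-1`/`end`.
#'
#' @param chromSizes named numeric vector (or 2-column data.frame name,size)
#'   of chromosome lengths in bp.
#' @param centromeres optional named numeric vector of centromere midpoints
#'   in bp; chromosomes absent from it get a single "whole" arm.
#' @param binSize bin width in bp (> 0).
#' @return GRanges with metadata columns `arm` ("p","q" or "whole") and
#'   `binIndex` (0-based rank within arm).
#' @examples
#' makeBins(c(chr1 = 10e6), binSize = 1e6)
#' @export
makeBins <- function(chromSizes, centromeres = NULL, binSize) {
  if (is.data.frame(chromSizes))
    chromSizes <- stats::setNames(chromSizes[[2]], chromSizes[[1]])
  stopifnot(binSize > 0, all(chromSizes > 0))
  out <- list()
  for (chrom in names(chromSizes)) {
    L <- chromSizes[[chrom]]
    cen <- if (!is.null(centromeres) && chrom %in% names(centromeres))
      centromeres[[chrom]] else NA_real_
    if (!is.na(cen) && (cen <= 0 || cen >= L))
      stop("centromere outside chromosome ", chrom)
    arms <- if (is.na(cen)) list(whole = c(0, L))
            else list(p = c(0, cen), q = c(cen, L))
    for (arm in names(arms)) {
      a0 <- arms[[arm]][1]; a1 <- arms[[arm]][2]
      nb <- ceiling((a1 - a0) / binSize - 1e-9)
      starts <- a0 + binSize * (seq_len(nb) - 1)
      ends <- pmin(starts + binSize, a1)
      out[[paste(chrom, arm)]] <- GRanges(
        chrom, IRanges(start = starts + 1, end = ends),
        arm = arm, binIndex = seq_along(starts) - 1L)
    }
  }
  gr <- unlist(methods::as(out, "GRangesList"), use.names = FALSE)
  S4Vectors::metadata(gr)$binSize <- binSize
  gr
}

#' Bin size of a binning produced by makeBins
#' @param bins GRanges from [makeBins()]
#' @return bin width in bp
#' @export
binSize <- function(bins) {
  bs <- S4Vectors::metadata(bins)$binSize
  if (is.null(bs)) bs <- max(width(bins))
  bs
}

#' Subset a binning to one arm
#' @param bins GRanges from [makeBins()]
#' @param chrom chromosome name
#' @param arm "p", "q" or "whole"
#' @export
armBins <- function(bins, chrom, arm) {
  gr <- bins[as.character(seqnames(bins)) == chrom & bins$arm == arm]
  S4Vectors::metadata(gr)$binSize <- binSize(bins)
  gr
}

#' Aggregate basepair-level records into genome bins
#'
#' With `stat = "mean"` the bin value is the coverage-weighted mean of
#' overlapping record values, where stretches of the bin covered by no record
#' contribute value 0 (fold-change tracks are dense; absence means no
#' signal, not missing).  `stat = "sum"` is the basepair-weighted sum
#' (value x overlap width).  `stat = "count"` counts records whose midpoint
#' falls inside the bin.
#'
#' @param x GRanges; for mean/sum a `score` column is required (bedGraph
#'   semantics), for count intervals suffice.
#' @param bins GRanges from [makeBins()].
#' @param stat "mean", "sum" or "count".
#' @param featureName,cellType labels for the returned track.
#' @return [SignalTrack-class]
#' @export
binSignal <- function(x, bins, stat = c("mean", "sum", "count"),
                      featureName = "signal", cellType = "NA") {
  stat <- match.arg(stat)
  n <- length(bins)
  vals <- numeric(n)
  if (stat == "count") {
    mid <- floor((start(x) - 1 + end(x)) / 2)  # 0-based midpoint bp
    midGr <- GRanges(seqnames(x), IRanges(mid + 1, width = 1))
    hits <- findOverlaps(midGr, bins)
    tab <- table(S4Vectors::subjectHits(hits))
    vals[as.integer(names(tab))] <- as.integer(tab)
  } else {
    if (is.null(x$score)) stop("records need a 'score' column for stat=", stat)
    hits <- findOverlaps(x, bins)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ow <- width(pintersect(x[qh], bins[sh]))
      contrib <- x$score[qh] * ow
      agg <- tapply(contrib, sh, sum)
      vals[as.integer(names(agg))] <- as.numeric(agg)
    }
    if (stat == "mean") vals <- vals / width(bins)
  }
  newSignalTrack(bins, vals, featureName, cellType)
}

#' Per-bin GC content track
#'
#' From a precomputed table the values are used as given (and checked to lie
#' in \[0,1\]).  From sequences, the GC fraction among non-N bases of each
#' bin is computed; bins with no informative base are masked.
#'
#' @param x either a data.frame with columns chrom,start,end,gc (0-based
#'   half-open, one row per bin, same order as `bins`), or a named
#'   `Biostrings::DNAStringSet` (one sequence per chromosome).
#' @param bins GRanges from [makeBins()].
#' @return [SignalTrack-class] named "GC" with values in \[0,1\].
#' @export
gcTrack <- function(x, bins) {
  n <- length(bins)
  if (is.data.frame(x)) {
    if (nrow(x) != n) stop("GC table must have one row per bin")
    gc <- as.numeric(x$gc)
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) stop("GC values must lie in [0,1]")
    return(newSignalTrack(bins, gc, "GC"))
  }
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA-based GC computation")
  gc <- numeric(n); mask <- logical(n)
  for (i in seq_len(n)) {
    chrom <- as.character(seqnames(bins)[i])
    seq <- Biostrings::subseq(x[[chrom]], start(bins)[i], end(bins)[i])
    f <- Biostrings::alphabetFrequency(seq)
    inf <- sum(f[c("A", "C", "G", "T")])
    if (inf == 0) { mask[i] <- TRUE; gc[i] <- NA_real_ }
    else gc[i] <- sum(f[c("G", "C")]) / inf
  }
  newSignalTrack(bins, gc, "GC", mask = mask)
}
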