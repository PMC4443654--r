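#' Subset a SignalTrack to one chromosome arm
#'
#' @param track [SignalTrack-class] over a multi-arm binning
#' @param chrom chromosome name
#' @param arm arm id ("p", "q" or "whole")
#' @return [SignalTrack-class] over the arm's bins
#' @export
trackForArm <- function(track, chrom, arm) {
  sel <- as.character(seqnames(track@bins)) == chrom & track@bins$arm == arm
  gr <- track@bins[sel]
  S4Vectors::metadata(gr)$binSize <- binSize(track@bins)
  new("SignalTrack", bins = gr, values = track@values[sel],
      featureName = track@featureName, cellType = track@cellType,
      mask = track@mask[sel])
}

#' Concatenate per-arm eigenvectors into a genome-wide track
#'
#' Stitches the per-arm compartment eigenvectors (computed independently
#' per arm) back onto a full binning, in the order of `bins`.
#'
#' @param eigs list of [Eigenvector-class], one per arm, in bin order
#' @param bins full GRanges binning whose length equals the summed arm
#'   lengths
#' @return [Eigenvector-class] over `bins` (eigenvalue = NA: arm-specific)
#' @export
combineArmEigenvectors <- function(eigs, bins) {
  values <- unlist(lapply(eigs, function(e) e@values))
  mask <- unlist(lapply(eigs, function(e) e@mask))
  if (length(values) != length(bins))
    stop("arm eigenvector lengths do not sum to the binning length")
  new("Eigenvector", values = values, mask = mask, bins = bins,
      signAnchor = eigs[[1]]@signAnchor, eigenvalue = NA_real_)
}

#' Run the compartment pipeline on every arm of a simulated dataset
#'
#' Convenience wrapper used throughout the examples and tests: applies
#' [compartmentPipeline()] to each arm's contact map of one cell type of a
#' [simulateChromatin()] object, using the simulated GC track as the sign
#' anchor, and returns per-arm results plus the genome-wide stitched
#' eigenvector and calls.
#'
#' @param sim [simulateChromatin()] output
#' @param ct cell type index
#' @return list: `arms` (per-arm [compartmentPipeline()] outputs), `eig`
#'   (genome-wide [Eigenvector-class]), `calls` (genome-wide)
#' @export
simCompartments <- function(sim, ct = 1) {
  arms <- lapply(seq_len(sim$cfg$nArms), function(a) {
    cm <- sim$contacts[[ct]][[a]]
    armI <- sim$states$arm == a
    gcArm <- new("SignalTrack", bins = binsOf(cm),
                 values = signalValues(sim$gc)[armI], featureName = "GC",
                 cellType = "NA", mask = binMask(sim$gc)[armI])
    compartmentPipeline(cm, gcArm)
  })
  eig <- combineArmEigenvectors(lapply(arms, `[[`, "eig"), sim$bins)
  list(arms = arms, eig = eig, calls = callCompartments(eig))
}
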