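# Shared fixtures, memoised so expensive simulations are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Default-condition simulation (1-Mb scale) used across acceptance checks.
defaultSim <- function(seed = 42) {
  fixture(paste0("defaultSim", seed), function() {
    simulateChromatin(simConfig(), seed = seed)
  })
}

# Compartment pipelines for all cell types of the default simulation.
defaultPipelines <- function(seed = 42) {
  fixture(paste0("defaultPipes", seed), function() {
    sim <- defaultSim(seed)
    lapply(seq_len(sim$cfg$nCellTypes), function(ct) simCompartments(sim, ct))
  })
}

# 40-kb-scale simulation for TAD-boundary work: 1-Mb mean TADs and multi-Mb
# compartment runs expressed in 40-kb bins.
tadScaleSim <- function(seed = 11) {
  fixture(paste0("tadSim", seed), function() {
    simulateChromatin(
      simConfig(binSize = 4e4, tadMeanLen = 25, persistence = 0.995,
                nArms = 1, nCellTypes = 2),
      seed = seed)
  })
}

tinyBins <- function(n = 20, binSize = 1e6, chrom = "chrT") {
  makeBins(stats::setNames(n * binSize, chrom), binSize = binSize)
}

# planted state as +/-1 per bin for one cell type
plantedSign <- function(sim, ct = 1) {
  ifelse(sim$states$states[, ct] == "A", 1, -1)
}

recallWithin <- function(planted, called, tol = 1) {
  if (!length(planted)) return(NA_real_)
  mean(vapply(planted, function(p) any(abs(called - p) <= tol), TRUE))
}

# planted TAD classes with well-separated signature feature profiles
archetypeFixture <- function(seed = 71, nTad = 60) {
  set.seed(seed)
  classes <- sample(c("active", "null", "PcG"), nTad, replace = TRUE)
  centres <- list(active = c(DNase = 3, H3K9me3 = 0.3, H3K27me3 = 0.5),
                  null = c(DNase = 0.3, H3K9me3 = 3, H3K27me3 = 0.4),
                  PcG = c(DNase = 0.5, H3K9me3 = 0.4, H3K27me3 = 3))
  lens <- sample(3:8, nTad, replace = TRUE)
  ends <- cumsum(lens); starts <- c(1, head(ends, -1) + 1)
  summ <- data.frame(tad = seq_len(nTad), startBin = starts, endBin = ends,
                     nBins = lens)
  for (f in c("DNase", "H3K9me3", "H3K27me3"))
    summ[[f]] <- vapply(classes, function(cl) centres[[cl]][f], 0) +
      rnorm(nTad, 0, 0.1)
  list(summary = summ, classes = classes, nBins = max(ends))
}
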