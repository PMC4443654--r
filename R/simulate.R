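## Synthetic multi-cell-type genomes with planted ground truth: two-state
## compartment structure, nested TAD partitions, state-dependent feature
## tracks with boundary-localised peaks/dips, distance-decaying Hi-C counts
## with compartment checkerboard + TAD-block enrichment and multiplicative
## per-bin biases, and compartment-tied enhancer annotations.

#' Default feature panel for the simulator
#'
#' Twelve chromatin-feature archetypes: eight compartment-informative tracks
#' (higher mean in A than B), two boundary-peaked tracks with no compartment
#' effect (CTCF/POL2-like), one boundary-dipped track anticorrelated with
#' the A state (H3K9me3-like), and one flat uninformative control.
#' `boundaryAmp` is the kernel height added at a boundary bin (sign +
#' peak / - dip), `boundaryWidth` its half-width in bins.
#'
#' @return data.frame with columns name, meanA, meanB, noiseSd, boundaryAmp,
#'   boundaryWidth.
#' @export
defaultFeatures <- function() {
  data.frame(
    name = c("DNase", "H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3", "H2AZ",
             "YY1", "EP300", "CTCF", "POL2", "H3K9me3", "INPUT"),
    meanA = c(2.5, 2.0, 2.2, 2.4, 1.8, 1.6, 1.5, 1.7, 1.2, 1.0, 0.6, 1.0),
    meanB = c(0.6, 0.7, 0.5, 0.6, 0.8, 0.7, 0.6, 0.5, 1.2, 1.0, 2.2, 1.0),
    noiseSd = rep(0.5, 12),
    boundaryAmp = c(0, 0, 0, 0, 0, 0, 0, 0, 2, 1.5, -1.5, 0),
    boundaryWidth = c(0, 0, 0, 0, 0, 0, 0, 0, 3, 3, 3, 0),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic genome.  Defaults: two
#' chromosome arms of 1000 bins at 1 Mb, three cell types, compartment
#' persistence 0.98 (geometric state runs of ~50 bins), mean TAD length 10
#' bins, twelve features ([defaultFeatures()]), contact decay exponent 1,
#' same-compartment affinity 0.3, same-TAD boost 0.5, lognormal bias sd 0.3,
#' 5e6 expected contacts per cell type, and 5% of bins in cell-type-specific
#' (altered) compartment runs.
#'
#' @param nBins bins per arm
#' @param nArms number of arms (one chromosome split at a centromere when 2)
#' @param binSize bp per bin
#' @param nCellTypes number of cell types (>= 2; 3 for variability analyses)
#' @param persistence per-bin probability of staying in the same compartment
#' @param tadMeanLen mean TAD length in bins
#' @param features feature panel as in [defaultFeatures()]
#' @param decayExponent contact distance-decay exponent alpha > 0
#' @param compartmentAffinity same-state contact multiplier epsilon >= 0
#' @param tadBoost same-TAD contact multiplier tau >= 0
#' @param biasSd sd of log-normal per-bin visibility biases
#' @param depth expected total contact count per cell type
#' @param switchFraction fraction of bins whose compartment is flipped in
#'   exactly one cell type
#' @param switchRunLen mean length (bins) of a flipped run
#' @param rSpecific expected cell-type-specific enhancers per altered-open bin
#' @param rShared expected shared enhancers per constitutive-A bin
#' @param rBaseline expected cell-type-specific enhancers per A bin anywhere
#' @param gcBase,gcEffect,gcNoiseSd GC track: base fraction, A-state
#'   increment, and noise sd
#' @return a `simConfig` list
#' @export
simConfig <- function(nBins = 1000, nArms = 2, binSize = 1e6, nCellTypes = 3,
                      persistence = 0.98, tadMeanLen = 10,
                      features = defaultFeatures(), decayExponent = 1,
                      compartmentAffinity = 0.3, tadBoost = 0.5,
                      biasSd = 0.3, depth = 5e6, switchFraction = 0.05,
                      switchRunLen = 5, rSpecific = 3, rShared = 1,
                      rBaseline = 0.5, gcBase = 0.4, gcEffect = 0.06,
                      gcNoiseSd = 0.01) {
  cfg <- list(nBins = nBins, nArms = nArms, binSize = binSize,
              nCellTypes = nCellTypes, persistence = persistence,
              tadMeanLen = tadMeanLen, features = features,
              decayExponent = decayExponent,
              compartmentAffinity = compartmentAffinity, tadBoost = tadBoost,
              biasSd = biasSd, depth = depth,
              switchFraction = switchFraction, switchRunLen = switchRunLen,
              rSpecific = rSpecific, rShared = rShared,
              rBaseline = rBaseline, gcBase = gcBase, gcEffect = gcEffect,
              gcNoiseSd = gcNoiseSd)
  stopifnot(nBins >= 50, nArms %in% 1:2, nCellTypes >= 2,
            persistence > 0, persistence < 1, decayExponent > 0,
            compartmentAffinity >= 0, tadBoost >= 0, biasSd >= 0,
            switchFraction >= 0, switchFraction < 1,
            all(is.finite(features$boundaryAmp)))
  if (depth <= 0) stop("depth must be positive")
  class(cfg) <- "simConfig"
  cfg
}

## deterministic sub-seed per stage so stages can be re-run independently
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

simBins <- function(cfg) {
  L <- cfg$nBins * cfg$binSize
  if (cfg$nArms == 2)
    makeBins(c(chrS = 2 * L), centromeres = c(chrS = L), binSize = cfg$binSize)
  else
    makeBins(c(chrS = L), binSize = cfg$binSize)
}

#' Simulate per-cell-type compartment states
#'
#' A base two-state Markov chain (symmetric persistence) is drawn per arm and
#' shared by all cell types; then contiguous runs covering ~`switchFraction`
#' of bins are each flipped in exactly one cell type, creating altered
#' open/closed regions.
#'
#' @param cfg [simConfig()]
#' @param seed integer seed
#' @return list: `base` (character A/B per bin), `states` (bins x cell types
#'   matrix of "A"/"B"), `altered` (data.frame bin ranges with cellType and
#'   direction "open"/"closed"), `arm` (arm id per bin).
#' @export
simulateStates <- function(cfg, seed = 1) {
  set.seed(stageSeed(seed, "states"))
  nTot <- cfg$nBins * cfg$nArms
  arm <- rep(seq_len(cfg$nArms), each = cfg$nBins)
  base <- character(nTot)
  for (a in seq_len(cfg$nArms)) {
    s <- integer(cfg$nBins)
    s[1] <- sample(0:1, 1)
    stay <- stats::runif(cfg$nBins - 1) < cfg$persistence
    for (i in 2:cfg$nBins) s[i] <- if (stay[i - 1]) s[i - 1] else 1L - s[i - 1]
    base[arm == a] <- c("B", "A")[s + 1]
  }
  states <- matrix(base, nTot, cfg$nCellTypes)
  colnames(states) <- paste0("CT", seq_len(cfg$nCellTypes))
  altered <- data.frame(start = integer(0), end = integer(0),
                        cellType = character(0), direction = character(0))
  target <- round(cfg$switchFraction * nTot)
  flipped <- logical(nTot)
  guard <- 0
  while (sum(flipped) < target && guard < 10000) {
    guard <- guard + 1
    len <- 1 + stats::rgeom(1, 1 / cfg$switchRunLen)
    st <- sample.int(nTot - len + 1, 1)
    idx <- st:(st + len - 1)
    if (any(flipped[idx]) || length(unique(arm[idx])) > 1) next
    ## require a homogeneous base run so the flip is a clean altered region
    if (length(unique(base[idx])) > 1) next
    ct <- sample.int(cfg$nCellTypes, 1)
    flip <- ifelse(base[idx] == "A", "B", "A")
    states[idx, ct] <- flip
    flipped[idx] <- TRUE
    altered <- rbind(altered, data.frame(
      start = st, end = st + len - 1, cellType = colnames(states)[ct],
      direction = if (base[st] == "B") "open" else "closed"))
  }
  list(base = base, states = states, altered = altered, arm = arm)
}

#' Simulate per-cell-type TAD partitions
#'
#' Shared breakpoints with geometric inter-breakpoint lengths (mean
#' `tadMeanLen`) are drawn per arm, then unioned per cell type with that
#' cell type's compartment state-change points, so every compartment
#' boundary is also a TAD boundary.  If `tadMeanLen >= nBins` no random
#' breakpoints are drawn.
#'
#' @param cfg [simConfig()]
#' @param st output of [simulateStates()]
#' @param seed integer seed
#' @return list over cell types of lists over arms of sorted integer
#'   breakpoints (local 1..nBins-1 indices: boundary between bins k-1 and k
#'   recorded as k).
#' @export
simulateTads <- function(cfg, st, seed = 1) {
  set.seed(stageSeed(seed, "tads"))
  n <- cfg$nBins
  shared <- lapply(seq_len(cfg$nArms), function(a) {
    if (cfg$tadMeanLen >= n) return(integer(0))
    bp <- integer(0); pos <- 0
    repeat {
      pos <- pos + 1 + stats::rgeom(1, 1 / cfg$tadMeanLen)
      if (pos >= n) break
      bp <- c(bp, pos)
    }
    bp
  })
  lapply(seq_len(cfg$nCellTypes), function(ct) {
    lapply(seq_len(cfg$nArms), function(a) {
      s <- st$states[st$arm == a, ct]
      changes <- which(s[-1] != s[-n])  # boundary index k (local, 1..n-1)
      sort(unique(c(shared[[a]], changes)))
    })
  })
}

triKernel <- function(d, width) if (width <= 0) as.numeric(d == 0) else pmax(0, 1 - abs(d) / width)

## bias-free expected contact structure of one arm in one cell type
lambdaStructure <- function(cfg, st, tads, ct, a) {
  n <- cfg$nBins
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  decay <- ifelse(D == 0, 0, D^(-cfg$decayExponent))
  s <- st$states[st$arm == a, ct]
  bp <- tads[[ct]][[a]]
  tadId <- cumsum(c(1, as.integer(seq_len(n - 1) %in% bp)))
  lam <- decay *
    (1 + cfg$compartmentAffinity * outer(s, s, "==")) *
    (1 + cfg$tadBoost * outer(tadId, tadId, "=="))
  diag(lam) <- 0
  lam
}

#' Identifiable planted biases of a simulated contact map
#'
#' Matrix balancing can only recover per-bin factors up to the balancing
#' decomposition of the expected matrix: on a finite arm, the bias-free
#' contact structure (distance decay truncated at the arm ends, plus
#' compartment/TAD factors) itself balances to non-uniform per-bin factors
#' e_i.  The identifiable planted bias at bin i is therefore b_i * e_i,
#' where b_i is the planted visibility factor.  This helper computes e by
#' iteratively correcting the noiseless structure matrix and returns b * e,
#' the quantity an unbiased balancing estimator converges to.
#'
#' @param sim [simulateChromatin()] output (with contacts)
#' @param ct cell type index
#' @param a arm index
#' @return numeric per-bin identifiable bias vector
#' @export
plantedEffectiveBiases <- function(sim, ct = 1, a = 1) {
  lam <- lambdaStructure(sim$cfg, sim$states, sim$tads, ct, a)
  bins <- binsOf(sim$contacts[[ct]][[a]])
  ic <- iceCorrect(newContactMatrix(lam * (sim$cfg$depth / sum(lam)), bins),
                   maxIter = 500)
  sim$biases[[a]] * biasEstimates(ic)
}

#' Simulate chromatin feature tracks
#'
#' value(bin) = state mean + boundary kernel terms + Gaussian noise, floored
#' at 0.  The boundary kernel is triangular, centred on the boundary bin
#' (the first bin of the new domain), applied at every TAD breakpoint of
#' that cell type (which include all compartment changes).
#'
#' @param cfg [simConfig()]
#' @param st output of [simulateStates()]
#' @param tads output of [simulateTads()]
#' @param seed integer seed
#' @param bins optional GRanges (defaults to the config's binning)
#' @return list over cell types of lists over features of [SignalTrack-class].
#' @export
simulateFeatureTracks <- function(cfg, st, tads, seed = 1, bins = simBins(cfg)) {
  set.seed(stageSeed(seed, "tracks"))
  n <- cfg$nBins
  fts <- cfg$features
  lapply(seq_len(cfg$nCellTypes), function(ct) {
    perArmBp <- tads[[ct]]
    tr <- lapply(seq_len(nrow(fts)), function(f) {
      vals <- numeric(0)
      for (a in seq_len(cfg$nArms)) {
        s <- st$states[st$arm == a, ct]
        v <- ifelse(s == "A", fts$meanA[f], fts$meanB[f])
        if (fts$boundaryAmp[f] != 0) {
          w <- fts$boundaryWidth[f]
          for (k in perArmBp[[a]]) {
            lo <- max(1, k + 1 - w); hi <- min(n, k + 1 + w)
            v[lo:hi] <- v[lo:hi] +
              fts$boundaryAmp[f] * triKernel((lo:hi) - (k + 1), w)
          }
        }
        vals <- c(vals, v)
      }
      vals <- pmax(0, vals + stats::rnorm(length(vals), 0, fts$noiseSd[f]))
      newSignalTrack(bins, vals, fts$name[f], paste0("CT", ct))
    })
    stats::setNames(tr, fts$name)
  })
}

#' Simulate the GC-content track
#'
#' GC is cell-type invariant and tied to the consensus (base) compartment
#' state: A-state bins are GC-richer by `gcEffect`.
#'
#' @inheritParams simulateFeatureTracks
#' @return [SignalTrack-class] named "GC".
#' @export
simulateGc <- function(cfg, st, seed = 1, bins = simBins(cfg)) {
  set.seed(stageSeed(seed, "gc"))
  gc <- cfg$gcBase + cfg$gcEffect * (st$base == "A") +
    stats::rnorm(length(st$base), 0, cfg$gcNoiseSd)
  newSignalTrack(bins, pmin(1, pmax(0, gc)), "GC")
}

#' Simulate Hi-C contact matrices
#'
#' Expected counts lambda_ij are proportional to
#' |i-j|^-alpha * (1 + eps * same-state) * (1 + tau * same-TAD) * b_i * b_j
#' with log-normal biases b (shared across cell types, per arm), scaled so
#' each arm matrix's expected total equals `depth`, then Poisson-sampled
#' symmetrically with a zero diagonal.
#'
#' @inheritParams simulateFeatureTracks
#' @return list: `contacts` = list over cell types of lists over arms of raw
#'   [ContactMatrix-class]; `biases` = list over arms of planted bias vectors.
#' @export
simulateContacts <- function(cfg, st, tads, seed = 1, bins = simBins(cfg)) {
  set.seed(stageSeed(seed, "contacts"))
  n <- cfg$nBins
  biases <- lapply(seq_len(cfg$nArms), function(a)
    exp(stats::rnorm(n, 0, cfg$biasSd)))
  lambdas <- lapply(seq_len(cfg$nCellTypes), function(ct) {
    lapply(seq_len(cfg$nArms), function(a) {
      lam <- lambdaStructure(cfg, st, tads, ct, a) *
        outer(biases[[a]], biases[[a]])
      lam
    })
  })
  armGr <- lapply(seq_len(cfg$nArms), function(a) {
    gr <- bins[st$arm == a]
    S4Vectors::metadata(gr)$binSize <- cfg$binSize
    gr
  })
  contacts <- lapply(seq_len(cfg$nCellTypes), function(ct) {
    lapply(seq_len(cfg$nArms), function(a) {
      lam <- lambdas[[ct]][[a]] * (cfg$depth / sum(lambdas[[ct]][[a]]))
      up <- upper.tri(lam)
      counts <- matrix(0, n, n)
      counts[up] <- stats::rpois(sum(up), lam[up])
      counts <- counts + t(counts)
      newContactMatrix(counts, armGr[[a]])
    })
  })
  list(contacts = contacts, biases = biases)
}

#' Simulate enhancer annotations tied to compartment state
#'
#' Cell-type-specific enhancers are planted at rate `rSpecific` per bin in
#' altered-open bins (A in exactly that cell type) and at rate `rBaseline`
#' in every A bin of each cell type (at cell-type-unique positions, hence
#' specific); shared enhancers at rate `rShared` in constitutive-A bins, at
#' identical positions in all cell types.
#'
#' @inheritParams simulateFeatureTracks
#' @return GRanges with metadata columns `name` ("enhancer") and `cellType`.
#' @export
simulateAnnotations <- function(cfg, st, seed = 1, bins = simBins(cfg)) {
  set.seed(stageSeed(seed, "annotations"))
  w <- max(200, round(cfg$binSize / 100))
  nTot <- length(bins)
  chrom <- as.character(seqnames(bins))
  plant <- function(binIdx, rate, cts) {
    ## returns data.frame of intervals; same positions reused for all cts
    out <- list()
    for (b in binIdx) {
      k <- stats::rpois(1, rate)
      if (k == 0) next
      off <- sort(sample.int(max(1, width(bins)[b] - w), k, replace = TRUE))
      for (ct in cts)
        out[[length(out) + 1]] <- data.frame(
          chrom = chrom[b], start = start(bins)[b] + off,
          end = start(bins)[b] + off + w - 1, cellType = ct)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  nA <- rowSums(st$states == "A")
  cts <- colnames(st$states)
  recs <- list()
  constitutiveA <- which(nA == cfg$nCellTypes)
  recs$shared <- plant(constitutiveA, cfg$rShared, cts)
  for (ct in seq_along(cts)) {
    aBins <- which(st$states[, ct] == "A")
    recs[[paste0("base", ct)]] <- plant(aBins, cfg$rBaseline, cts[ct])
    openBins <- which(st$states[, ct] == "A" & nA == 1)
    recs[[paste0("spec", ct)]] <- plant(openBins, cfg$rSpecific, cts[ct])
  }
  recs <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(recs))
    return(GRanges(name = character(0), cellType = character(0)))
  GRanges(recs$chrom, IRanges(recs$start, recs$end),
          name = "enhancer", cellType = recs$cellType)
}

#' Simulate a complete multi-cell-type chromatin dataset
#'
#' Runs all stages with deterministic per-stage sub-seeds derived from one
#' global seed, so the whole object is reproducible from `(cfg, seed)` and
#' individual stages can be re-run independently.
#'
#' @param cfg [simConfig()]
#' @param seed integer seed
#' @param contacts set FALSE to skip contact-map simulation (feature-only
#'   studies are much cheaper)
#' @return a `chromatinSim` list with elements `cfg`, `seed`, `bins`,
#'   `states` (the [simulateStates()] output), `tads`, `tracks`, `gc`,
#'   `contacts`, `biases`, `annotations`, and `truth` — a compact
#'   ground-truth summary (per-cell-type states, TAD breakpoints, planted
#'   biases, names of compartment-informative features, altered regions).
#' @export
simulateChromatin <- function(cfg = simConfig(), seed = 1, contacts = TRUE) {
  bins <- simBins(cfg)
  st <- simulateStates(cfg, seed)
  tads <- simulateTads(cfg, st, seed)
  tracks <- simulateFeatureTracks(cfg, st, tads, seed, bins)
  gc <- simulateGc(cfg, st, seed, bins)
  ann <- simulateAnnotations(cfg, st, seed, bins)
  cm <- if (contacts) simulateContacts(cfg, st, tads, seed, bins) else
    list(contacts = NULL, biases = NULL)
  informative <- cfg$features$name[cfg$features$meanA != cfg$features$meanB]
  out <- list(cfg = cfg, seed = seed, bins = bins, states = st, tads = tads,
              tracks = tracks, gc = gc, contacts = cm$contacts,
              biases = cm$biases, annotations = ann,
              truth = list(states = st$states, base = st$base,
                           altered = st$altered, tads = tads,
                           biases = cm$biases,
                           informativeFeatures = informative,
                           enhancers = ann))
  class(out) <- "chromatinSim"
  out
}

#' @export
print.chromatinSim <- function(x, ...) {
  cat(sprintf("chromatinSim: %d arms x %d bins @ %g bp, %d cell types, %d features (seed %d)\n",
              x$cfg$nArms, x$cfg$nBins, x$cfg$binSize, x$cfg$nCellTypes,
              nrow(x$cfg$features), x$seed))
  invisible(x)
}
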