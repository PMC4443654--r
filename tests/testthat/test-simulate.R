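test_that("simulated compartment states follow the Markov-chain geometry", {
  # no cell-type switching -> identical states everywhere
  cfg0 <- simConfig(nBins = 200, nArms = 1, switchFraction = 0)
  st0 <- simulateStates(cfg0, seed = 3)
  expect_true(all(st0$states[, 1] == st0$states[, 2]))
  expect_equal(nrow(st0$altered), 0)

  # persistence near 1 -> a single state per arm
  cfgP <- simConfig(nBins = 100, nArms = 1, persistence = 1 - 1e-9,
                    switchFraction = 0)
  stP <- simulateStates(cfgP, seed = 3)
  expect_length(unique(stP$base), 1)

  # geometric run lengths: mean approx 1/(1-p) = 50 at p = 0.98
  cfgR <- simConfig(nBins = 10000, nArms = 1, persistence = 0.98,
                    switchFraction = 0)
  stR <- simulateStates(cfgR, seed = 8)
  runs <- rle(stR$base)$lengths
  expect_gt(mean(runs), 45)
  expect_lt(mean(runs), 55)
})

test_that("TAD partitions include all compartment changes and hit the mean length", {
  cfg <- simConfig(nBins = 10000, nArms = 1, tadMeanLen = 10,
                   persistence = 0.999, switchFraction = 0)
  st <- simulateStates(cfg, seed = 5)
  tads <- simulateTads(cfg, st, seed = 5)
  bp <- tads[[1]][[1]]
  s <- st$states[, 1]
  changes <- which(s[-1] != s[-length(s)])
  expect_true(all(changes %in% bp))
  lens <- diff(c(0, bp, cfg$nBins))
  expect_lt(abs(mean(lens) - 10) / 10, 0.15)

  # degenerate limit: one TAD when no breaks are possible
  cfg1 <- simConfig(nBins = 100, nArms = 1, tadMeanLen = 200,
                    persistence = 1 - 1e-9, switchFraction = 0)
  st1 <- simulateStates(cfg1, seed = 1)
  expect_length(simulateTads(cfg1, st1, seed = 1)[[1]][[1]], 0)
})

test_that("feature tracks are state step functions plus boundary kernels", {
  cfg <- simConfig(nBins = 60, nArms = 1, nCellTypes = 2, tadMeanLen = 1e4,
                   persistence = 1 - 1e-9, switchFraction = 0)
  cfg$features <- data.frame(name = c("flat", "peak"), meanA = c(2, 1),
                             meanB = c(0.5, 1), noiseSd = c(0, 0),
                             boundaryAmp = c(0, 2), boundaryWidth = c(0, 3))
  st <- simulateStates(cfg, seed = 2)
  # hand-plant one boundary for the kernel check
  tads <- list(list(30L), list(30L))
  tr <- simulateFeatureTracks(cfg, st, tads, seed = 2)
  flat <- signalValues(tr[[1]]$flat)
  expect_length(unique(flat), 1)   # constant state -> one level, no noise
  peak <- signalValues(tr[[1]]$peak)
  expect_equal(peak[31], 1 + 2)        # centre bin elevated by the amplitude
  expect_equal(peak[31 - 3], 1)        # +/- width bins unaffected
  expect_equal(peak[31 + 3], 1)
  expect_equal(peak[31 + 1], 1 + 2 * (1 - 1/3))

  # two-state step function when states vary
  cfgS <- simConfig(nBins = 200, nArms = 1, switchFraction = 0)
  cfgS$features <- data.frame(name = "step", meanA = 2, meanB = 0.5,
                              noiseSd = 0, boundaryAmp = 0, boundaryWidth = 0)
  stS <- simulateStates(cfgS, seed = 4)
  trS <- simulateFeatureTracks(cfgS, stS, simulateTads(cfgS, stS, 4), seed = 4)
  v <- signalValues(trS[[1]]$step)
  expect_setequal(unique(v), c(2, 0.5))
  expect_equal(v, ifelse(stS$states[, 1] == "A", 2, 0.5))
})

test_that("the uninformative feature is uncorrelated with compartment state", {
  cfg <- simConfig(nBins = 10000, nArms = 1, binSize = 1e4,
                   switchFraction = 0)
  st <- simulateStates(cfg, seed = 6)
  tads <- simulateTads(cfg, st, seed = 6)
  tr <- simulateFeatureTracks(cfg, st, tads, seed = 6)
  s <- ifelse(st$states[, 1] == "A", 1, -1)
  expect_lt(abs(cor(signalValues(tr[[1]]$INPUT), s)), 0.05)
  # and the H3K9me3 analogue is anticorrelated
  expect_lt(cor(signalValues(tr[[1]]$H3K9me3), s), -0.5)
})

test_that("contact maps follow the planted distance decay and are reproducible", {
  cfg <- simConfig(nBins = 300, nArms = 1, nCellTypes = 2,
                   compartmentAffinity = 0, tadBoost = 0, biasSd = 0,
                   depth = 2e6)
  st <- simulateStates(cfg, seed = 9)
  tads <- simulateTads(cfg, st, seed = 9)
  simA <- simulateContacts(cfg, st, tads, seed = 9)
  simB <- simulateContacts(cfg, st, tads, seed = 9)
  m <- contactCounts(simA$contacts[[1]][[1]])
  expect_identical(m, contactCounts(simB$contacts[[1]][[1]]))  # determinism
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) == 0))

  # empirical mean at a distance within 3 Poisson SD of lambda(d)
  n <- cfg$nBins
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  decay <- ifelse(D == 0, 0, D^-1)
  lam <- decay * (cfg$depth / sum(decay))
  for (d in c(1, 5, 20)) {
    idx <- which(D == d & upper.tri(D))
    expLam <- lam[idx[1]]
    se <- sqrt(expLam / length(idx))
    expect_lt(abs(mean(m[idx]) - expLam), 3 * se + 1e-9)
  }

  expect_error(simConfig(depth = -1), "depth")
})

test_that("the whole simulation is reproducible from (cfg, seed)", {
  cfg <- simConfig(nBins = 120, nArms = 2, nCellTypes = 2, depth = 2e5)
  s1 <- simulateChromatin(cfg, seed = 13)
  s2 <- simulateChromatin(cfg, seed = 13)
  expect_identical(s1$states$states, s2$states$states)
  expect_identical(signalValues(s1$tracks[[2]]$CTCF),
                   signalValues(s2$tracks[[2]]$CTCF))
  expect_identical(contactCounts(s1$contacts[[1]][[2]]),
                   contactCounts(s2$contacts[[1]][[2]]))
  expect_identical(start(s1$annotations), start(s2$annotations))
})

test_that("enhancer planting follows the compartment-state rules", {
  # no switching -> no altered regions, so no rSpecific enhancers
  cfg <- simConfig(nBins = 300, nArms = 1, switchFraction = 0,
                   rBaseline = 0, rShared = 0, rSpecific = 5)
  st <- simulateStates(cfg, seed = 21)
  ann <- simulateAnnotations(cfg, st, seed = 21, bins = chromarch:::simBins(cfg))
  expect_length(ann, 0)

  # with switching, specific enhancers land in altered-open bins of the
  # active cell type only
  cfg2 <- simConfig(nBins = 300, nArms = 1, switchFraction = 0.1,
                    rBaseline = 0, rShared = 0, rSpecific = 5)
  st2 <- simulateStates(cfg2, seed = 22)
  bins2 <- chromarch:::simBins(cfg2)
  ann2 <- simulateAnnotations(cfg2, st2, seed = 22, bins = bins2)
  nA <- rowSums(st2$states == "A")
  openBins <- which(nA == 1)
  hit <- GenomicRanges::findOverlaps(ann2, bins2)
  expect_true(all(S4Vectors::subjectHits(hit) %in% openBins))
})
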