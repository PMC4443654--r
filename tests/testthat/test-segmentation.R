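mkEig <- function(values, mask = rep(FALSE, length(values))) {
  vals <- values
  vals[mask] <- NA_real_
  new("Eigenvector", values = vals, mask = mask,
      bins = tinyBins(length(values)), signAnchor = "GC", eigenvalue = 1)
}

test_that("Baum-Welch recovers a well-separated Gaussian mixture chain", {
  set.seed(31)
  n <- 600
  s <- integer(n); s[1] <- 1
  for (i in 2:n) s[i] <- if (runif(1) < 0.98) s[i - 1] else 3 - s[i - 1]
  x <- rnorm(n, mean = c(1, -1)[s], sd = 0.1)
  fit <- fitTwoStateHMM(mkEig(x))
  expect_lt(abs(fit@means[1] - 1), 0.05)
  expect_lt(abs(fit@means[2] + 1), 0.05)
  expect_gt(fit@transition[1, 1], 0.95)
  expect_lt(fit@transition[1, 1], 0.995)
  expect_gt(fit@transition[2, 2], 0.95)
})

test_that("state relabelling leaves Viterbi boundaries unchanged", {
  set.seed(32)
  x <- c(rnorm(50, 1, 0.2), rnorm(50, -1, 0.2))
  eig <- mkEig(x)
  fit <- fitTwoStateHMM(eig)
  seg <- viterbiSegment(fit, eig)
  # permute state labels by hand
  perm <- c(2, 1)
  flipped <- new("GaussianHMM", initial = fit@initial[perm],
                 transition = fit@transition[perm, perm],
                 means = fit@means[perm], sds = fit@sds[perm],
                 stateNames = fit@stateNames[perm], logLik = fit@logLik,
                 converged = TRUE)
  seg2 <- viterbiSegment(flipped, eig)
  expect_equal(boundaryPositions(seg$boundaries),
               boundaryPositions(seg2$boundaries))
  expect_equal(seg$path, seg2$path)
})

test_that("Viterbi handles trivial and noiseless segmentations", {
  eigPos <- mkEig(rep(0.5, 30))
  fitP <- suppressWarnings(fitTwoStateHMM(eigPos))
  expect_length(boundaryPositions(viterbiSegment(fitP, eigPos)$boundaries), 0)

  x <- c(rep(1, 50), rep(-1, 50)) + rnorm(100, 0, 0.01)
  eig <- mkEig(x)
  seg <- viterbiSegment(fitTwoStateHMM(eig), eig)
  expect_equal(boundaryPositions(seg$boundaries), 50L)
})

test_that("Viterbi path beats the planted path in log-probability (brute force)", {
  # exhaustive optimality check on small instances
  logProb <- function(model, x, path) {
    lp <- log(model@initial[path[1]]) +
      dnorm(x[1], model@means[path[1]], model@sds[path[1]], log = TRUE)
    for (t in 2:length(x)) {
      lp <- lp + log(model@transition[path[t - 1], path[t]]) +
        dnorm(x[t], model@means[path[t]], model@sds[path[t]], log = TRUE)
    }
    lp
  }
  set.seed(33)
  for (rep in 1:5) {
    n <- 10
    truth <- sample(1:2, n, replace = TRUE)
    x <- rnorm(n, c(0.8, -0.8)[truth], 0.5)
    model <- new("GaussianHMM", initial = c(0.5, 0.5),
                 transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2),
                 means = c(0.8, -0.8), sds = c(0.5, 0.5),
                 stateNames = c("A", "B"), logLik = 0, converged = TRUE)
    vp <- viterbiPath(model, x)
    grid <- as.matrix(expand.grid(rep(list(1:2), n)))
    best <- max(apply(grid, 1, function(p) logProb(model, x, p)))
    expect_equal(logProb(model, x, vp), best, tolerance = 1e-10)
    expect_gte(logProb(model, x, vp), logProb(model, x, truth))
  }
})

test_that("masked bins are bridged by the transition structure", {
  x <- c(rep(1, 40), rep(-1, 40))
  mask <- rep(FALSE, 80); mask[35:45] <- TRUE
  eig <- mkEig(x + rnorm(80, 0, 0.05), mask)
  fit <- fitTwoStateHMM(eig)
  seg <- viterbiSegment(fit, eig)
  expect_length(seg$path, 80)
  expect_true(all(!is.na(seg$path)))
  expect_length(boundaryPositions(seg$boundaries), 1)
})

test_that("directionality index follows its defining formula", {
  # bin with upstream sum 10 and downstream sum 30 -> DI = +10
  n <- 9; centre <- 5
  m <- matrix(0, n, n)
  m[centre, centre - 2] <- 4; m[centre, centre - 1] <- 6    # A = 10
  m[centre, centre + 1] <- 10; m[centre, centre + 2] <- 20  # B = 30
  m <- m + t(m)
  cm <- chromarch:::newContactMatrix(m, tinyBins(n))
  di <- directionalityIndex(cm, window = 4e6)
  expect_equal(di$di[centre], 10)

  # antisymmetry: swapping upstream/downstream flips the sign
  mR <- m[n:1, n:1]
  diR <- directionalityIndex(chromarch:::newContactMatrix(mR, tinyBins(n)),
                             window = 4e6)
  expect_equal(diR$di[n + 1 - centre], -10)

  # symmetric neighbourhood (A == B) and empty bins give DI = 0
  expect_equal(di$di[1], 0)
  m2 <- matrix(0, n, n)
  m2[centre, centre - 1] <- 5; m2[centre, centre + 1] <- 5
  m2 <- m2 + t(m2)
  di2 <- directionalityIndex(chromarch:::newContactMatrix(m2, tinyBins(n)),
                             window = 4e6)
  expect_equal(di2$di[centre], 0)

  expect_error(directionalityIndex(cm, window = 1e6), "2 bins")
})

test_that("a single noiseless TAD edge yields one boundary at the edge", {
  n <- 60; edge <- 30
  tad <- c(rep(1, edge), rep(2, n - edge))
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- ifelse(D == 0, 0, D^-1) * (1 + 2 * outer(tad, tad, "=="))
  cm <- chromarch:::newContactMatrix(lam * 1e4, tinyBins(n))
  di <- directionalityIndex(cm, window = 10e6)
  tb <- callTadBoundaries(di, resolution = 1e6)
  expect_equal(boundaryPositions(tb), edge)
})

test_that("TAD recovery fails to chance level on distance-shuffled maps", {
  sim <- tadScaleSim()
  cm <- maskLowCoverage(sim$contacts[[1]][[1]])
  ic <- iceCorrect(cm)
  # distance-preserving shuffle: permute values within each diagonal
  m <- contactCounts(ic); n <- nrow(m)
  set.seed(35)
  sh <- matrix(0, n, n)
  for (d in 1:(n - 1)) {
    i <- seq_len(n - d)
    v <- m[cbind(i, i + d)]
    v <- sample(v)
    sh[cbind(i, i + d)] <- v; sh[cbind(i + d, i)] <- v
  }
  cmSh <- chromarch:::newContactMatrix(sh, binsOf(ic), mask = binMask(ic),
                                       corrected = TRUE)
  tbSh <- callTadBoundaries(directionalityIndex(cmSh, 2e6), resolution = 4e4)
  planted <- sim$tads[[1]][[1]]
  recSh <- recallWithin(planted, boundaryPositions(tbSh))
  # chance recovery given the number of shuffled calls
  k <- length(boundaryPositions(tbSh))
  chance <- 1 - (1 - 3 / (sim$cfg$nBins - 1))^k
  expect_lt(recSh, chance + 0.1)
})

test_that("boundary concordance is exact on identity and tolerance examples", {
  bs <- function(p, n = 100) chromarch:::newBoundarySet(p, "TAD", 4e4, n)
  self <- boundaryConcordance(bs(c(10, 40, 70)), bs(c(10, 40, 70)),
                              toleranceBins = 0, nNull = 100, seed = 1)
  expect_equal(self$matchedFraction, 1)

  xy <- boundaryConcordance(bs(10), bs(12), toleranceBins = 1, nNull = 100,
                            seed = 1)
  expect_equal(xy$matchedFraction, 0)
  xy2 <- boundaryConcordance(bs(10), bs(12), toleranceBins = 2, nNull = 100,
                             seed = 1)
  expect_equal(xy2$matchedFraction, 1)

  expect_error(boundaryConcordance(bs(integer(0)), bs(10)), "empty")
})

test_that("uniform random boundary sets match the analytic null", {
  n <- 500; t <- 1
  set.seed(36)
  X <- sort(sample.int(n - 1, 30))
  Y <- sort(sample.int(n - 1, 40))
  bs <- function(p) chromarch:::newBoundarySet(p, "TAD", 4e4, n)
  cc <- boundaryConcordance(bs(X), bs(Y), toleranceBins = t, nNull = 1000,
                            seed = 2, minGap = 1)
  analytic <- 1 - (1 - (2 * t + 1) / (n - 1))^length(Y)
  expect_lt(abs(cc$nullMean - analytic), 0.02)
  expect_lt(abs(cc$matchedFraction - analytic),
            3 * sd(cc$nullFractions) + 0.02)
  # KS on matched structure: a set equal to its target is far from the null
  ccSelf <- boundaryConcordance(bs(X), bs(X), toleranceBins = t,
                                nNull = 300, seed = 3, minGap = 1)
  expect_gt(ccSelf$ksD, 0.5)
  expect_lt(ccSelf$ksP, 1e-6)
})
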