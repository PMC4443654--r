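mkFm <- function(x, y, cellType = "CT1") {
  structure(list(x = x, y = y, bins = seq_along(y), cellType = cellType,
                 resolution = 1e6, nDropped = 0), class = "featureMatrix")
}

test_that("assembleFeatures joins tracks on unmasked bins", {
  bins <- tinyBins(10)
  tr <- lapply(c("a", "b"), function(nm)
    chromarch:::newSignalTrack(bins, rnorm(10), nm))
  gc <- chromarch:::newSignalTrack(bins, runif(10, 0.3, 0.6), "GC")
  mask <- rep(FALSE, 10); mask[4] <- TRUE
  eig <- new("Eigenvector", values = replace(rnorm(10), 4, NA), mask = mask,
             bins = bins, signAnchor = "GC", eigenvalue = 1)
  fm <- assembleFeatures(tr, gc, eig)
  expect_equal(dim(fm$x), c(9, 3))
  expect_equal(colnames(fm$x), c("a", "b", "GC"))
  expect_false(4 %in% fm$bins)          # masked bin's row absent
  expect_error(assembleFeatures(c(tr, tr[1]), gc, eig), "duplicate")
})

test_that("the forest recovers a copied feature and ignores pure noise", {
  set.seed(51)
  n <- 1000
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fmCopy <- mkFm(x, x[, 1])
  mCopy <- trainForest(fmCopy, seed = 52)
  expect_gt(mCopy$oobMetrics$pcc, 0.95)

  fmNoise <- mkFm(x, rnorm(n))
  mNoise <- trainForest(fmNoise, seed = 52)
  expect_lt(abs(mNoise$oobMetrics$pcc), 0.1)
  # pure-noise model: all importances near zero
  imp <- variableImportance(mNoise)
  expect_true(all(abs(imp$pctIncMSE) < 10))

  # determinism: same seed, same OOB predictions
  mCopy2 <- trainForest(fmCopy, seed = 52)
  expect_identical(mCopy$oobPredictions, mCopy2$oobPredictions)

  expect_error(trainForest(mkFm(x, rep(1, n))), "constant")
  expect_error(trainForest(mkFm(x[1:20, ], rnorm(20))), "50")
})

test_that("evaluateModel reproduces its defining edge cases", {
  set.seed(53)
  truth <- rnorm(1000)
  perfect <- evaluateModel(truth, truth)
  expect_equal(perfect$pcc, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$accuracyPct, 100)
  expect_equal(perfect$auroc, 1)

  inverted <- evaluateModel(-truth, truth)
  expect_equal(inverted$pcc, -1)
  expect_equal(inverted$auroc, 0)

  rnd <- evaluateModel(rnorm(1000), truth)
  expect_lt(abs(rnd$auroc - 0.5), 0.05)
})

test_that("OOB accuracy does not exceed in-bag accuracy", {
  set.seed(54)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1] - x[, 2] + rnorm(n, 0, 0.7)
  worse <- 0
  for (s in 1:20) {
    m <- trainForest(mkFm(x, y), seed = s)
    inBag <- cor(as.numeric(predict(m$rf, x)), y)
    if (m$oobMetrics$pcc > inBag) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("permutation importance separates planted from noise features", {
  set.seed(55)
  n <- 800
  x <- cbind(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3))
  colnames(x) <- c(paste0("real", 1:3), paste0("noise", 1:3))
  y <- x[, 1] + x[, 2] - x[, 3] + rnorm(n, 0, 0.4)
  fm <- mkFm(x, y)
  m <- trainForest(fm, seed = 56)
  imp <- variableImportance(m)
  realImp <- imp$pctIncMSE[grep("real", imp$feature)]
  noiseImp <- imp$pctIncMSE[grep("noise", imp$feature)]
  expect_gt(min(realImp), max(noiseImp))
  expect_true(all(abs(noiseImp) < 5))
  # adding an irrelevant duplicate-noise column leaves the real ranks' order
  x2 <- cbind(x, dup = rnorm(n))
  imp2 <- variableImportance(trainForest(mkFm(x2, y), seed = 56))
  ord1 <- imp$feature[order(-imp$pctIncMSE)][1:3]
  ord2 <- imp2$feature[order(-imp2$pctIncMSE)][1:3]
  expect_equal(ord1, ord2)
})

test_that("cross-application transfers when rules are shared, flips when inverted", {
  set.seed(57)
  n <- 800
  mk <- function(flip = 1) {
    x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- flip * (x[, 1] + 0.8 * x[, 2]) + rnorm(n, 0, 0.5)
    mkFm(x, y)
  }
  fmA <- mk(); fmB <- mk(); fmInv <- mk(flip = -1)
  m <- trainForest(fmA, seed = 58)
  # applying back to the training data: in-bag optimism, decline approx 0
  selfAp <- crossApply(m, fmA)
  expect_lt(abs(selfAp$declinePcc), 0.1)
  # shared rules: decline well under 25%
  crossAp <- crossApply(m, fmB)
  expect_lt(crossAp$declinePcc, 0.25)
  # inverted rules: the cross-applied PCC flips sign
  invAp <- crossApply(m, fmInv)
  expect_lt(invAp$metrics$pcc, -0.5)
})

test_that("baselines: OLS nails linear targets, the forest wins on XOR", {
  skip_if_not_installed("mixOmics")
  set.seed(59)
  n <- 600
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  yLin <- x %*% c(1, -0.5, 0.25, 0) + rnorm(n, 0, 0.05)
  bl <- baselineModels(mkFm(x, as.numeric(yLin)), seed = 60, ncompMax = 4)
  expect_gt(bl$ols$pcc, 0.99)
  expect_gt(bl$pls$pcc, 0.98)

  # collinear features: PLS matches or beats OLS cross-validated RMSE
  xc <- cbind(x[, 1], x[, 1] + rnorm(n, 0, 0.01),
              x[, 1] + rnorm(n, 0, 0.01), x[, 2])
  colnames(xc) <- paste0("c", 1:4)
  yc <- xc[, 1] + rnorm(n, 0, 0.3)
  blc <- baselineModels(mkFm(xc, yc), seed = 60, ncompMax = 4)
  expect_lte(blc$pls$rmse, blc$ols$rmse * 1.05)

  # XOR-style target: forest beats OLS
  yx <- sign(x[, 1]) * sign(x[, 2]) + rnorm(n, 0, 0.3)
  fmX <- mkFm(x, yx)
  blx <- baselineModels(fmX, seed = 60, ncompMax = 4)
  mx <- trainForest(fmX, seed = 60)
  expect_gt(mx$oobMetrics$pcc, blx$ols$pcc + 0.3)
})

test_that("coarse models transfer to repeated fine-resolution rows", {
  set.seed(61)
  n <- 400
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- x[, 1] - x[, 2] + rnorm(n, 0, 0.3)
  m <- trainForest(mkFm(x, y), seed = 62)
  rep10 <- rep(seq_len(n), each = 10)
  fineX <- x[rep10, ] + rnorm(n * 10 * 5, 0, 0.05)
  fineFm <- mkFm(fineX, y[rep10])
  mr <- multiResolutionApply(m, fineFm)
  expect_gt(mr$pccRatio, 0.85)
  # noiseless repetition predicts identically per block
  mrN <- multiResolutionApply(m, mkFm(x[rep10, ], y[rep10]))
  expect_equal(matrix(mrN$predictions, nrow = 10)[1, ],
               matrix(mrN$predictions, nrow = 10)[10, ])
  # row order invariance
  perm <- sample(nrow(fineX))
  mrP <- multiResolutionApply(m, mkFm(fineX[perm, ], y[rep10][perm]))
  expect_equal(mrP$metrics$pcc, mr$metrics$pcc)
})

test_that("stratified fits expose target-noise differences between subgroups", {
  set.seed(63)
  n <- 900
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  groups <- rep(c("low", "high"), each = n / 2)
  noise <- ifelse(groups == "low", 0.2, 1.5)
  y <- x[, 1] + rnorm(n, 0, noise)
  fits <- variabilityStratifiedFit(mkFm(x, y), groups, seed = 64)
  expect_gt(fits$low$metrics$pcc, fits$high$metrics$pcc)
  expect_error(variabilityStratifiedFit(mkFm(x, y),
                                        c(rep("a", 20), rep("b", n - 20))),
               "fewer than 50")
})
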