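#' Assemble a feature matrix for compartment modelling
#'
#' Inner join of feature tracks, the GC track and the eigenvector on bins
#' that are unmasked everywhere; rows with any non-finite value are dropped
#' and counted.
#'
#' @param tracks list of [SignalTrack-class] (unique feature names)
#' @param gc [SignalTrack-class] GC track (appended as feature "GC"); NULL
#'   to omit
#' @param eig [Eigenvector-class] target
#' @return a `featureMatrix` list: `x` (numeric matrix rows = bins, columns
#'   = features), `y` (eigenvector), `bins` (row bin indices, 1-based),
#'   `cellType`, `resolution`, `nDropped`
#' @export
assembleFeatures <- function(tracks, gc = NULL, eig) {
  if (!is.null(gc)) tracks <- c(tracks, list(gc))
  nms <- vapply(tracks, featureName, "")
  if (anyDuplicated(nms)) stop("duplicate feature names")
  x <- do.call(cbind, lapply(tracks, signalValues))
  colnames(x) <- nms
  keep <- !eig@mask & !Reduce(`|`, lapply(tracks, binMask))
  ok <- keep & apply(is.finite(x), 1, all) & is.finite(eig@values)
  structure(list(x = x[ok, , drop = FALSE], y = eig@values[ok],
                 bins = which(ok),
                 cellType = tracks[[1]]@cellType,
                 resolution = binSize(eig@bins),
                 nDropped = sum(keep) - sum(ok)),
            class = "featureMatrix")
}

#' Train a random-forest eigenvector model
#'
#' Random forest regression with ntree = 200 and mtry = floor(n/3) (12 for
#' the canonical 36-feature panel), bootstrap rows per tree.  Out-of-bag
#' predictions and OOB evaluation metrics are stored with the model.
#'
#' @param fm [assembleFeatures()] output (>= 50 rows)
#' @param seed RNG seed (forest growth is bit-reproducible given the seed)
#' @param nTree number of trees
#' @param nPerm permutations per tree for the stored importance measure
#' @return a `forestModel` list: `rf` (randomForest fit), `oobPredictions`,
#'   `oobMetrics`, `trainCellType`, `seed`, `nPerm`
#' @export
trainForest <- function(fm, seed = 1, nTree = 200, nPerm = 1) {
  if (nrow(fm$x) < 50) stop("need at least 50 rows")
  if (stats::var(fm$y) == 0) stop("constant target")
  mtry <- max(1, floor(ncol(fm$x) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(fm$x, fm$y, ntree = nTree, mtry = mtry,
                                   importance = TRUE, nPerm = nPerm)
  structure(list(rf = rf, oobPredictions = rf$predicted,
                 oobMetrics = evaluateModel(rf$predicted, fm$y),
                 trainCellType = fm$cellType, seed = seed, nPerm = nPerm),
            class = "forestModel")
}

#' Evaluate continuous compartment predictions
#'
#' PCC and RMSE on the continuous values; thresholding both at 0 (A >= 0)
#' gives the classification accuracy; the AUROC scores the continuous
#' predictions against the thresholded truth (fixed direction, so inverted
#' predictors score below 0.5).
#'
#' @param pred,truth numeric vectors
#' @return list: `pcc`, `rmse`, `accuracyPct`, `auroc`
#' @export
evaluateModel <- function(pred, truth) {
  ok <- is.finite(pred) & is.finite(truth)
  pred <- pred[ok]; truth <- truth[ok]
  cls <- truth >= 0
  auroc <- if (length(unique(cls)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = cls, predictor = pred,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  list(pcc = stats::cor(pred, truth),
       rmse = sqrt(mean((pred - truth)^2)),
       accuracyPct = 100 * mean((pred >= 0) == cls),
       auroc = auroc)
}

#' Permutation variable importance (%IncMSE)
#'
#' Mean decrease in out-of-bag accuracy under within-tree permutation of
#' each feature, expressed as the percentage increase over the model's OOB
#' MSE and averaged over trees and `nPerm` permutation repetitions.
#'
#' @param model [trainForest()] output
#' @param fm the training [assembleFeatures()] output (needed to refit when
#'   `nPerm` differs from the stored model's)
#' @param nPerm permutation repetitions per tree
#' @param seed RNG seed used if a refit is needed
#' @return data.frame: feature, pctIncMSE, rank (1 = most important)
#' @export
variableImportance <- function(model, fm = NULL, nPerm = model$nPerm,
                               seed = model$seed) {
  rf <- model$rf
  if (nPerm != model$nPerm) {
    if (is.null(fm)) stop("fm required to recompute importance with new nPerm")
    model <- trainForest(fm, seed = seed, nTree = rf$ntree, nPerm = nPerm)
    rf <- model$rf
  }
  rawInc <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  oobMse <- mean((model$oobPredictions - rf$y)^2)
  pct <- 100 * rawInc / oobMse
  data.frame(feature = names(pct), pctIncMSE = unname(pct),
             rank = rank(-pct, ties.method = "first"))
}

#' Apply a trained model to another cell type
#'
#' Predicts the other cell type's bins without retraining and reports the
#' relative decline of the PCC against the training cell type's native OOB
#' PCC.
#'
#' @param model [trainForest()] output
#' @param fmOther [assembleFeatures()] output for the other cell type (same
#'   feature columns)
#' @return list: `metrics` ([evaluateModel()] output), `declinePcc`
#'   (relative, (native - cross)/native), `predictions`
#' @export
crossApply <- function(model, fmOther) {
  pred <- as.numeric(stats::predict(model$rf, fmOther$x))
  metrics <- evaluateModel(pred, fmOther$y)
  native <- model$oobMetrics$pcc
  list(metrics = metrics, declinePcc = (native - metrics$pcc) / native,
       predictions = pred)
}

cvFolds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Linear and partial-least-squares baselines
#'
#' Ordinary least squares on all features and PLS regression with the number
#' of components chosen by 10-fold cross-validated RMSE (1..`ncompMax`).
#' Both are scored on 10-fold cross-validated predictions (the out-of-bag
#' notion has no analogue here).
#'
#' @param fm [assembleFeatures()] output
#' @param seed RNG seed for the fold split
#' @param ncompMax largest PLS component count tried
#' @param nFolds folds
#' @return list: `ols` (metrics), `pls` (metrics + `ncomp`), `folds`
#' @export
baselineModels <- function(fm, seed = 1, ncompMax = 15, nFolds = 10) {
  n <- nrow(fm$x); p <- ncol(fm$x)
  folds <- cvFolds(n, nFolds, seed)
  df <- data.frame(y = fm$y, fm$x, check.names = TRUE)
  olsPred <- numeric(n)
  for (f in seq_len(nFolds)) {
    fit <- stats::lm(y ~ ., data = df[folds != f, , drop = FALSE])
    olsPred[folds == f] <- stats::predict(fit, df[folds == f, , drop = FALSE])
  }
  ols <- evaluateModel(olsPred, fm$y)
  pls <- NULL
  if (requireNamespace("mixOmics", quietly = TRUE)) {
    ncompMax <- min(ncompMax, p, n - 2)
    plsPred <- matrix(NA_real_, n, ncompMax)
    for (f in seq_len(nFolds)) {
      tr <- folds != f
      fit <- mixOmics::pls(fm$x[tr, , drop = FALSE], fm$y[tr],
                           ncomp = ncompMax, mode = "regression",
                           scale = TRUE)
      pr <- stats::predict(fit, fm$x[!tr, , drop = FALSE])$predict
      plsPred[!tr, ] <- pr[, 1, ]
    }
    rmses <- sqrt(colMeans((plsPred - fm$y)^2))
    best <- which.min(rmses)
    pls <- c(evaluateModel(plsPred[, best], fm$y), list(ncomp = best))
  }
  list(ols = ols, pls = pls, folds = folds)
}

#' Apply a coarse-resolution model at fine resolution
#'
#' Straight application of a model trained on coarse bins (e.g. 1 Mb) to a
#' fine-resolution feature matrix (e.g. 100 kb) with identical feature
#' columns.
#'
#' @param model [trainForest()] output (coarse)
#' @param fineFm [assembleFeatures()] output at fine resolution
#' @return list: `metrics`, `pccRatio` (fine PCC / native coarse OOB PCC),
#'   `predictions`
#' @export
multiResolutionApply <- function(model, fineFm) {
  pred <- as.numeric(stats::predict(model$rf, fineFm$x))
  metrics <- evaluateModel(pred, fineFm$y)
  list(metrics = metrics, pccRatio = metrics$pcc / model$oobMetrics$pcc,
       predictions = pred)
}

#' Independent forests per variability tertile
#'
#' Fits a separate random forest to each subgroup of bins (typically the
#' low/mid/high structural-variability tertiles) and reports per-subgroup
#' OOB metrics.
#'
#' @param fm [assembleFeatures()] output
#' @param tertiles factor/character per row of `fm$x`
#' @param seed RNG seed
#' @return named list per subgroup: `model`, `metrics` (OOB)
#' @export
variabilityStratifiedFit <- function(fm, tertiles, seed = 1) {
  stopifnot(length(tertiles) == nrow(fm$x))
  out <- list()
  for (g in unique(as.character(tertiles))) {
    idx <- which(tertiles == g)
    if (length(idx) < 50) stop("subgroup '", g, "' has fewer than 50 rows")
    sub <- fm
    sub$x <- fm$x[idx, , drop = FALSE]; sub$y <- fm$y[idx]
    sub$bins <- fm$bins[idx]
    m <- trainForest(sub, seed = seed)
    out[[g]] <- list(model = m, metrics = m$oobMetrics)
  }
  out
}
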