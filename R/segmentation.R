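#' Fit a two-state HMM to a compartment eigenvector
#'
#' Baum-Welch with Gaussian emissions on the unmasked eigenvector values,
#' initialised from the sign split (state means = mean of positive /
#' negative values).  The state with the larger emission mean is labelled A
#' and stored first, so downstream state indices are stable.
#'
#' @param eig [Eigenvector-class] (>= 20 unmasked bins)
#' @param seed unused placeholder kept for interface stability (the fit is
#'   deterministic given the initialisation)
#' @param maxIter,tol Baum-Welch stopping rule
#' @return [GaussianHMM-class] with stateNames c("A","B")
#' @export
fitTwoStateHMM <- function(eig, seed = 1, maxIter = 500, tol = 1e-6) {
  x <- eig@values
  v <- x[!is.na(x)]
  if (length(v) < 20) stop("need at least 20 unmasked bins")
  pos <- v[v >= 0]; neg <- v[v < 0]
  if (!length(pos) || !length(neg)) {
    warning("degenerate eigenvector: all values of one sign; single-state fit")
    m <- mean(v); s <- max(stats::sd(v), 1e-3)
    init <- c(m + s, m - s)
    sds <- c(s, s)
  } else {
    init <- c(mean(pos), mean(neg))
    sds <- c(max(stats::sd(pos), 1e-3), max(stats::sd(neg), 1e-3))
  }
  fit <- fitGaussianHMM(x, means = init, sds = sds,
                        transition = matrix(c(0.95, 0.05, 0.05, 0.95), 2),
                        maxIter = maxIter, tol = tol,
                        stateNames = c("A", "B"))
  if (fit@means[1] < fit@means[2]) {   # keep A = larger mean in slot 1
    perm <- c(2, 1)
    fit@means <- fit@means[perm]; fit@sds <- fit@sds[perm]
    fit@initial <- fit@initial[perm]
    fit@transition <- fit@transition[perm, perm]
  }
  fit
}

#' Viterbi segmentation of an eigenvector into compartments
#'
#' Decodes the most probable A/B state path (masked bins are bridged on the
#' transition structure) and records a compartment boundary at every A<->B
#' transition of the path.
#'
#' @param model [GaussianHMM-class] from [fitTwoStateHMM()]
#' @param eig [Eigenvector-class]
#' @return list: `path` (character "A"/"B" per bin) and `boundaries`
#'   ([BoundarySet-class], btype "compartment")
#' @export
viterbiSegment <- function(model, eig) {
  p <- viterbiPath(model, eig@values)
  path <- model@stateNames[p]
  n <- length(path)
  pos <- which(path[-1] != path[-n])
  bs <- newBoundarySet(pos, "compartment", binSize(eig@bins), n)
  list(path = path, boundaries = bs)
}

#' Directionality index of a contact map
#'
#' For each bin, A = sum of contacts to upstream bins within the window,
#' B = downstream sum, E = (A+B)/2 and
#' DI = sign(B-A) * ((A-E)^2/E + (B-E)^2/E); DI = 0 when A = B or A+B = 0.
#' Positive DI marks downstream-biased bins (domain starts), negative DI
#' upstream-biased bins (domain ends).  Bins whose window is truncated by
#' the arm edge are computed on the truncated window and flagged.
#'
#' @param cm [ContactMatrix-class] (typically corrected)
#' @param window one-sided window in bp (default 2 Mb); must span >= 2 bins
#' @return list: `di` numeric per bin (NA at masked bins), `truncated`
#'   logical per bin, `windowBins` the window size in bins
#' @export
directionalityIndex <- function(cm, window = 2e6) {
  n <- nrow(cm@matrix)
  w <- floor(window / binSize(cm@bins))
  if (w < 2) stop("window must span at least 2 bins")
  di <- numeric(n); truncated <- logical(n)
  for (i in seq_len(n)) {
    up <- max(1, i - w):(i - 1)
    dn <- (i + 1):min(n, i + w)
    if (i == 1) up <- integer(0)
    if (i == n) dn <- integer(0)
    truncated[i] <- (i - w < 1) || (i + w > n)
    A <- if (length(up)) sum(cm@matrix[i, up]) else 0
    B <- if (length(dn)) sum(cm@matrix[i, dn]) else 0
    if (A + B == 0 || A == B) { di[i] <- 0; next }
    E <- (A + B) / 2
    di[i] <- sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  di[cm@mask] <- NA_real_
  list(di = di, truncated = truncated, windowBins = w)
}

#' Call TAD boundaries from a directionality-index track
#'
#' A three-state (upstream-biased / unbiased / downstream-biased) Gaussian
#' HMM is fitted by Baum-Welch to the variance-stabilised DI
#' (sign(DI) * sqrt|DI|: the DI is a signed chi-square-like statistic whose
#' heavy tails defeat Gaussian emissions on the raw scale), initialised
#' from the DI tertiles, and decoded by Viterbi.  A TAD boundary is
#' recorded where a downstream-biased run begins immediately after an
#' upstream-biased or unbiased run.  Because Viterbi smoothing suppresses
#' domains shorter than a few bins, an additional boundary is recorded at
#' any one-bin negative-to-positive DI flip whose magnitude exceeds
#' `flipFactor` times the fitted upstream-to-downstream state separation —
#' the same transition signature at higher temporal resolution.  Calls are
#' then snapped within +/- `snap` bins to the position with the steepest
#' upward DI change (the characteristic deep-negative-to-high-positive
#' flip at a domain edge), and boundaries closer than `minGap` bins are
#' merged, keeping the position with the stronger |DI|.
#'
#' @param di output of [directionalityIndex()]
#' @param resolution bin size in bp (for the BoundarySet record)
#' @param seed unused placeholder (deterministic given initialisation)
#' @param minGap minimum inter-boundary gap in bins (default 3)
#' @param snap localisation refinement radius in bins (0 disables)
#' @param flipFactor sign-flip sensitivity as a fraction of the fitted
#'   up-to-down state separation (larger = more conservative; Inf disables)
#' @return [BoundarySet-class] with btype "TAD"
#' @export
callTadBoundaries <- function(di, resolution = 1, seed = 1, minGap = 3,
                              snap = 2, flipFactor = 0.75) {
  x <- di$di
  y <- sign(x) * sqrt(abs(x))
  v <- y[!is.na(y)]
  q <- stats::quantile(v, c(1/6, 3/6, 5/6))
  spread <- max(stats::sd(v) / 2, 1e-3)
  fit <- fitGaussianHMM(y, means = as.numeric(q),
                        sds = rep(spread, 3),
                        stateNames = c("up", "none", "down"))
  ord <- order(fit@means)  # ensure up < none < down by mean
  fit@means <- fit@means[ord]; fit@sds <- fit@sds[ord]
  fit@initial <- fit@initial[ord]; fit@transition <- fit@transition[ord, ord]
  path <- viterbiPath(fit, y)   # 1=up, 2=none, 3=down
  n <- length(path)
  jump <- y[-1] - y[-n]              # jump[k] = y[k+1] - y[k]
  jump[is.na(jump)] <- -Inf
  ## a domain edge starts a downstream-biased run and/or ends an
  ## upstream-biased one; strong one-bin sign flips are the same signature
  ## at a resolution the smoothed path cannot reach
  sep <- fit@means[3] - fit@means[1]
  starts <- sort(unique(c(
    which(path[-1] == 3L & path[-n] != 3L),
    which(path[-n] == 1L & path[-1] != 1L),
    which(jump > flipFactor * sep & y[-n] < 0 & y[-1] > 0))))
  if (snap > 0 && length(starts)) {
    starts <- vapply(starts, function(k) {
      cand <- max(1L, k - snap):min(n - 1L, k + snap)
      cand[which.max(jump[cand])]
    }, 0L)
    starts <- sort(unique(starts))
  }
  if (length(starts) > 1) {
    keepPos <- starts[1]
    absDi <- function(k) { a <- abs(x[k + 1]); if (is.na(a)) 0 else a }
    for (k in starts[-1]) {
      last <- keepPos[length(keepPos)]
      if (k - last < minGap) {
        if (absDi(k) > absDi(last)) keepPos[length(keepPos)] <- k
      } else keepPos <- c(keepPos, k)
    }
    starts <- keepPos
  }
  newBoundarySet(starts, "TAD", resolution, n)
}

#' Boundary concordance between two boundary sets with a randomised null
#'
#' The matched fraction is the share of X boundaries having a Y boundary
#' within +/- `toleranceBins`.  The null re-places |Y| boundaries uniformly
#' at random over the valid positions (respecting a minimum gap of
#' `minGap` bins) `nNull` times and recomputes the fraction.  A
#' Kolmogorov-Smirnov test compares the observed distance-to-nearest-Y
#' distribution over X boundaries against the pooled null distances.
#'
#' @param setX,setY [BoundarySet-class] at the same resolution and arm size
#' @param toleranceBins matching tolerance (0 = same bin, 1 = adjacent bin)
#' @param nNull number of null replicates (>= 100 recommended)
#' @param seed RNG seed for the null placements
#' @param minGap min gap enforced in null placements (matches the caller's
#'   boundary-calling rule; default 3)
#' @return list: `matchedFraction`, `toleranceBins`, `nullFractions`,
#'   `nullMean`, `ksD`, `ksP`, `distances`
#' @export
boundaryConcordance <- function(setX, setY, toleranceBins = 1, nNull = 1000,
                                seed = 1, minGap = 3) {
  px <- setX@positions; py <- setY@positions
  if (!length(px) || !length(py)) stop("empty boundary set")
  if (setX@resolution != setY@resolution)
    stop("boundary sets must share a resolution")
  nBins <- setX@nBins
  distTo <- function(x, y) vapply(x, function(p) min(abs(p - y)), 0)
  dObs <- distTo(px, py)
  matched <- mean(dObs <= toleranceBins)
  set.seed(seed)
  k <- length(py)
  placeNull <- function() {
    for (try in 1:200) {
      cand <- sort(sample.int(nBins - 1, k))
      if (k == 1 || all(diff(cand) >= minGap)) return(cand)
    }
    cand  # dense sets: fall back on an unconstrained draw
  }
  nullFr <- numeric(nNull)
  nullD <- vector("list", nNull)
  for (r in seq_len(nNull)) {
    yr <- placeNull()
    dr <- distTo(px, yr)
    nullFr[r] <- mean(dr <= toleranceBins)
    nullD[[r]] <- dr
  }
  ks <- suppressWarnings(stats::ks.test(dObs, unlist(nullD)))
  list(matchedFraction = matched, toleranceBins = toleranceBins,
       nullFractions = nullFr, nullMean = mean(nullFr),
       ksD = unname(ks$statistic), ksP = ks$p.value, distances = dObs)
}
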