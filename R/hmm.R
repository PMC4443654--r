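## Gaussian hidden Markov model core: scaled forward-backward (Baum-Welch)
## and Viterbi decoding.  NA observations are treated as missing: their
## emission term is omitted, so the chain bridges masked bins on the
## transition structure alone.

emissionMatrix <- function(x, means, sds) {
  n <- length(x); k <- length(means)
  B <- matrix(1, n, k)
  ok <- !is.na(x)
  for (j in seq_len(k))
    B[ok, j] <- stats::dnorm(x[ok], means[j], sds[j])
  B[B < 1e-300] <- 1e-300
  B
}

forwardBackward <- function(x, initial, transition, means, sds) {
  n <- length(x); k <- length(means)
  B <- emissionMatrix(x, means, sds)
  alpha <- matrix(0, n, k); beta <- matrix(0, n, k); scal <- numeric(n)
  a <- initial * B[1, ]
  scal[1] <- sum(a); alpha[1, ] <- a / scal[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% transition) * B[t, ]
    scal[t] <- sum(a); alpha[t, ] <- a / scal[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1)
    beta[t, ] <- (transition %*% (B[t + 1, ] * beta[t + 1, ])) / scal[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(alpha = alpha, beta = beta, gamma = gamma, scal = scal, B = B,
       logLik = sum(log(scal)))
}

#' Fit a Gaussian hidden Markov model by Baum-Welch
#'
#' Expectation-maximisation on the scaled forward-backward recursions.
#' Missing observations (NA) contribute no emission term.  State order is
#' preserved from the initialisation (no relabelling), so initialise with
#' distinct means to pin state identity.
#'
#' @param x numeric observations (may contain NA).
#' @param means,sds,transition,initial initial parameter values; `means`
#'   determines the number of states.
#' @param maxIter,tol stop when the log-likelihood gain drops below `tol`
#'   (default 1e-6) or after `maxIter` iterations.
#' @param minSd lower bound on emission sds for numerical stability.
#' @param stateNames optional state labels.
#' @return [GaussianHMM-class]
#' @export
fitGaussianHMM <- function(x, means, sds, transition = NULL, initial = NULL,
                           maxIter = 500, tol = 1e-6, minSd = 1e-3,
                           stateNames = NULL) {
  k <- length(means)
  if (is.null(transition))
    transition <- matrix(0.05 / (k - 1), k, k) + diag(rep(0.95 - 0.05 / (k - 1), k))
  if (is.null(initial)) initial <- rep(1 / k, k)
  if (is.null(stateNames)) stateNames <- paste0("S", seq_len(k))
  sds <- pmax(sds, minSd)
  ok <- !is.na(x)
  prevLL <- -Inf; converged <- FALSE; fb <- NULL
  for (iter in seq_len(maxIter)) {
    fb <- forwardBackward(x, initial, transition, means, sds)
    if (is.finite(prevLL) && fb$logLik - prevLL < tol) { converged <- TRUE; break }
    prevLL <- fb$logLik
    n <- length(x)
    ## transition update
    num <- matrix(0, k, k)
    for (t in seq_len(n - 1)) {
      xi <- (fb$alpha[t, ] %o% (fb$B[t + 1, ] * fb$beta[t + 1, ])) * transition
      num <- num + xi / sum(xi)
    }
    transition <- num / rowSums(num)
    initial <- fb$gamma[1, ]
    ## emission update on observed positions only
    g <- fb$gamma[ok, , drop = FALSE]
    w <- colSums(g)
    means <- colSums(g * x[ok]) / w
    sds <- pmax(sqrt(colSums(g * (outer(x[ok], means, "-")^2)) / w), minSd)
  }
  new("GaussianHMM", initial = initial, transition = transition,
      means = means, sds = sds, stateNames = stateNames,
      logLik = fb$logLik, converged = converged)
}

#' Most probable state path (Viterbi)
#'
#' @param model [GaussianHMM-class]
#' @param x observations (NA allowed: bridged on transitions alone).
#' @return integer state path (1-based state indices, in the model's order).
#' @export
viterbiPath <- function(model, x) {
  n <- length(x); k <- length(model@means)
  logB <- log(emissionMatrix(x, model@means, model@sds))
  logT <- log(pmax(model@transition, 1e-300))
  delta <- matrix(-Inf, n, k); psi <- matrix(0L, n, k)
  delta[1, ] <- log(pmax(model@initial, 1e-300)) + logB[1, ]
  for (t in 2:n) {
    cand <- delta[t - 1, ] + logT   # k x k: from row, to col
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta[t, ] <- cand[cbind(psi[t, ], seq_len(k))] + logB[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}
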