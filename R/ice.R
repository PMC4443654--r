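#' Mask low-coverage bins of a contact map
#'
#' Bins with zero total contacts, or whose total is in the bottom `frac`
#' quantile of the nonzero totals, are flagged unusable before iterative
#' correction.
#'
#' @param cm [ContactMatrix-class]
#' @param frac fraction of nonzero-coverage bins to drop (default 0.02)
#' @return ContactMatrix with updated mask
#' @export
maskLowCoverage <- function(cm, frac = 0.02) {
  tot <- rowSums(cm@matrix)
  nz <- tot[tot > 0]
  thr <- if (length(nz)) stats::quantile(nz, frac) else Inf
  cm@mask <- cm@mask | tot == 0 | tot <= thr
  cm
}

#' Iterative correction (ICE) of a Hi-C contact map
#'
#' Alternately divides the matrix by its row/column scaling until the
#' coefficient of variation of the unmasked row sums drops below `tol`.
#' Masked rows and columns are zeroed and excluded throughout.  The
#' returned per-bin bias factors satisfy
#' `raw = corrected * outer(biases, biases)` on unmasked bins.
#'
#' @param cm raw [ContactMatrix-class] (mask set, e.g. by
#'   [maskLowCoverage()])
#' @param tol convergence tolerance on the row-sum coefficient of variation
#' @param maxIter maximum number of balancing iterations
#' @return corrected ContactMatrix with `biases` filled and `converged`
#'   flag; non-convergence raises a warning.
#' @export
iceCorrect <- function(cm, tol = 1e-5, maxIter = 200) {
  if (all(cm@mask)) stop("all bins are masked")
  keep <- !cm@mask
  W <- cm@matrix[keep, keep, drop = FALSE]
  b <- rep(1, sum(keep))
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    rs <- rowSums(W)
    cv <- stats::sd(rs) / mean(rs)
    if (is.finite(cv) && cv < tol) { converged <- TRUE; break }
    s <- rs / mean(rs)
    s[s == 0] <- 1
    W <- W / outer(s, s)
    b <- b * s
  }
  if (!converged)
    warning("iterative correction did not converge in ", maxIter,
            " iterations (row-sum CV ", signif(cv, 3), ")")
  out <- matrix(0, nrow(cm@matrix), ncol(cm@matrix))
  out[keep, keep] <- W
  biases <- rep(NA_real_, length(keep))
  biases[keep] <- b
  newContactMatrix(out, cm@bins, mask = cm@mask, corrected = TRUE,
                   biases = biases, converged = converged)
}
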