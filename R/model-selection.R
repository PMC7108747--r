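#' Bayesian Information Criterion for a Bernoulli mixture fit
#'
#' BIC(K) = loglik - (1/2) dim(K) log F, with the parameter-space dimension
#' dim(K) = K(N+2) under constrained (shared per-component) dispersion and
#' K(2N+1) under free dispersion.
#'
#' @param loglik observed-data log-likelihood at the estimate.
#' @param K number of components.
#' @param N number of genomes.
#' @param F number of gene families.
#' @param constrained dispersion mode.
#' @return BIC value (larger is better).
#' @export
bmmBIC <- function(loglik, K, N, F, constrained = TRUE) {
  if (F < 1) stop("F must be >= 1")
  if (!is.finite(loglik)) stop("loglik must be finite")
  d <- if (constrained) K * (N + 2) else K * (2 * N + 1)
  loglik - 0.5 * d * log(F)
}

#' Integrated Completed Likelihood
#'
#' ICL = BIC - H where H = -sum_i sum_k t_ik log t_ik is the classification
#' entropy of the posteriors (zero terms skipped). Hard posteriors give
#' ICL = BIC; fuzzier posteriors are penalized.
#'
#' @param bic BIC value from \code{\link{bmmBIC}}.
#' @param posterior row-normalized F x K posterior matrix.
#' @return ICL value (larger is better).
#' @export
bmmICL <- function(bic, posterior) {
  bic - posteriorEntropy(posterior)
}

posteriorEntropy <- function(posterior) {
  p <- posterior[posterior > 0]
  -sum(p * log(p))
}

#' Select the number of partitions K by ICL
#'
#' Runs short BinEM fits (default 10 EM steps, as in automatic K
#' determination) for each candidate K, computes ICL(K), and selects the
#' smallest K whose ICL lies within delta_ICL of the maximum, with
#' delta_ICL = deltaFrac * (max ICL - min ICL). The margin avoids choosing
#' a higher K that brings no significant ICL gain over a lower one.
#'
#' @param X a \linkS4class{PAMatrix} or binary matrix.
#' @param KGrid candidate K values (default 3..20).
#' @param emSteps EM iterations per short run (default 10).
#' @param deltaFrac fraction of the ICL range used as margin (default 0.05).
#' @param constrained dispersion mode.
#' @param seed accepted for interface stability; the triangular
#'   initialization makes the short runs deterministic.
#' @return a \linkS4class{KSelection}.
#' @export
selectK <- function(X, KGrid = 3:20, emSteps = 10, deltaFrac = 0.05,
                    constrained = TRUE, seed = NULL) {
  Xd <- paToDense(X)
  KGrid <- sort(unique(as.integer(KGrid)))
  KGrid <- KGrid[KGrid <= nrow(Xd)]
  if (!length(KGrid)) stop("no candidate K is <= the number of families")
  F <- nrow(Xd)
  N <- ncol(Xd)
  ll <- bic <- icl <- ent <- numeric(length(KGrid))
  for (q in seq_along(KGrid)) {
    fit <- runBinEM(Xd, KGrid[q], maxIter = emSteps,
                    constrained = constrained)
    ll[q] <- fit$loglik[length(fit$loglik)]
    bic[q] <- bmmBIC(ll[q], KGrid[q], N, F, constrained)
    ent[q] <- posteriorEntropy(fit$posterior)
    icl[q] <- bic[q] - ent[q]
  }
  delta <- deltaFrac * (max(icl) - min(icl))
  KHat <- KGrid[which(icl >= max(icl) - delta)[1]]
  new("KSelection", grid = KGrid, loglik = ll, bic = bic, icl = icl,
      entropy = ent, KHat = as.integer(KHat), deltaICL = delta)
}
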