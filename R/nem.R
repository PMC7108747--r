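# fuzzy NEM criterion: expected complete log-likelihood + entropy +
# beta * corrector * sum_{i~i'} w_{ii'} sum_k t_ik t_i'k
# (W holds each unordered pair twice, hence the 1/2)
nemCriterion <- function(T, base, W, bc) {
  tp <- T[T > 0]
  ent <- -sum(tp * log(tp))
  pair <- if (bc > 0) 0.5 * sum(T * as.matrix(W %*% T)) else 0
  sum(T * base) + ent + bc * pair
}

# symmetric F x F sparse weight matrix over the MRF-eligible edges
edgeWeightMatrix <- function(edges, familyIds) {
  i <- match(edges$from, familyIds)
  j <- match(edges$to, familyIds)
  if (anyNA(i) || anyNA(j))
    stop("graph contains families absent from the P/A matrix")
  F <- length(familyIds)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = c(edges$weight, edges$weight),
                       dims = c(F, F))
}

#' Mean-field E-step of the Neighboring EM
#'
#' Fixed-point iteration for the mean-field approximation of the hidden
#' Markov Random Field posterior: each round recomputes
#' t_ik proportional to pi_k exp(log f_k(x_i) + beta c sum_{i'~i} w_ii'
#' t_i'k) synchronously over all families and renormalizes rows, stopping
#' after \code{innerIters} rounds or when the largest posterior change is
#' below 1e-4. Each round is accepted only if it does not decrease the
#' fuzzy NEM criterion, which keeps the outer algorithm monotone.
#'
#' @param X a PAMatrix or binary matrix.
#' @param params a \linkS4class{BMMParams}.
#' @param edges MRF-eligible weighted edges (from \code{\link{mrfEdges}}).
#' @param TPrev previous F x K posterior (starting point of the coupling).
#' @param beta spatial regularity coefficient (>= 0; 0 disables the MRF).
#' @param corrector balance term F / sum of eligible edge weights.
#' @param innerIters fixed-point iteration budget (default 10).
#' @param innerTol stopping threshold on the max posterior change.
#' @return list with \code{posterior} and \code{criterion} (fuzzy NEM
#'   criterion at the returned posterior).
#' @export
meanFieldEStep <- function(X, params, edges, TPrev, beta = 2.5,
                           corrector = NULL, innerIters = 10,
                           innerTol = 1e-4) {
  X <- paToDense(X)
  base <- sweep(logDensityMatrix(X, params), 2L, log(params@pi), "+")
  haveEdges <- !is.null(edges) && nrow(edges) > 0 && beta > 0
  if (haveEdges) {
    W <- edgeWeightMatrix(edges, rownames(X))
    if (is.null(corrector)) corrector <- nrow(X) / sum(edges$weight)
    bc <- beta * corrector
  } else {
    W <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(nrow(X), nrow(X)))
    bc <- 0
  }
  T <- TPrev
  crit <- nemCriterion(T, base, W, bc)
  for (r in seq_len(max(1L, innerIters))) {
    field <- if (bc > 0) bc * as.matrix(W %*% T) else 0
    lp <- base + field
    Tnew <- exp(lp - rowLogSumExp(lp))
    critNew <- nemCriterion(Tnew, base, W, bc)
    if (critNew < crit - 1e-12) break  # keep the last non-decreasing state
    delta <- max(abs(Tnew - T))
    T <- Tnew
    crit <- critNew
    if (delta < innerTol) break
  }
  dimnames(T) <- list(rownames(X), NULL)
  list(posterior = T, criterion = crit)
}

#' Partition a pangenome by Neighboring EM (MRF-smoothed mixture)
#'
#' Alternates the mean-field E-step with the Bernoulli-mixture M-step from
#' the triangular initialization. The hidden MRF over the pangenome graph
#' favors graph neighbors sharing a partition; its strength is beta times a
#' corrector F / sum(w) over the MRF-eligible edges (both endpoints with
#' degree <= \code{maxDegree}), so smoothing stays balanced as pangenomes
#' grow. With beta = 0 (or no eligible edges) the procedure reduces exactly
#' to \code{\link{runBinEM}}.
#'
#' @param X a \linkS4class{PAMatrix} or binary matrix.
#' @param graph a \linkS4class{PangenomeGraph} over the same families.
#' @param K number of partitions.
#' @param beta spatial regularity coefficient (default 2.5).
#' @param maxDegree smoothing degree cap (default 10).
#' @param maxIter,tol outer convergence controls on the fuzzy NEM
#'   criterion.
#' @param constrained,epsFloor dispersion controls, as in
#'   \code{\link{runBinEM}}.
#' @param innerIters mean-field fixed-point budget per E-step.
#' @param seed accepted for interface stability; the algorithm is
#'   deterministic.
#' @return list with \code{params}, \code{posterior}, \code{partitioning}
#'   (a \linkS4class{Partitioning}) and \code{criterion} trace.
#' @export
runNEM <- function(X, graph, K, beta = 2.5, maxDegree = 10, maxIter = 100,
                   tol = 1e-6, constrained = TRUE, epsFloor = 1e-4,
                   innerIters = 10, seed = NULL) {
  Xd <- paToDense(X)
  fams <- rownames(Xd)
  if (K > nrow(Xd)) stop("K must not exceed the number of families")
  if (!is.null(graph)) {
    gfams <- graph@nodes$family_id
    if (!setequal(gfams, fams))
      stop("P/A matrix and graph must cover the same gene families")
    edges <- mrfEdges(graph, maxDegree)
  } else {
    edges <- NULL
  }
  corrector <- if (!is.null(edges) && nrow(edges) > 0)
    nrow(Xd) / sum(edges$weight) else 0
  params <- triangularInit(K, ncol(Xd), constrained, epsFloor)
  T <- matrix(1 / K, nrow(Xd), K, dimnames = list(fams, NULL))
  es <- meanFieldEStep(Xd, params, edges, T, beta, corrector, innerIters)
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    trace <- c(trace, es$criterion)
    params <- mStep(Xd, es$posterior, constrained, epsFloor)
    es2 <- meanFieldEStep(Xd, params, edges, es$posterior, beta, corrector,
                          innerIters)
    if (abs(es2$criterion - es$criterion) <
        tol * max(1, abs(es$criterion))) {
      es <- es2
      trace <- c(trace, es$criterion)
      break
    }
    es <- es2
  }
  srt <- sortComponentsByPresence(params, es$posterior)
  part <- assignPartitions(srt$posterior, fams)
  list(params = srt$params, posterior = srt$posterior,
       partitioning = part, criterion = trace)
}
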