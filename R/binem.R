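#' Triangular initialization of the Bernoulli mixture
#'
#' Sets pi_k = 1/K; mu rows are all-ones for k <= K/2 and all-zeros after,
#' so component 1 starts persistent-like and component K cloud-like (which
#' also fixes label switching). With s = 1/ceiling(K/2), the dispersions
#' rise then fall triangularly across components, rescaled by 1/2 so the
#' peak is 1/2 at the central components and every value respects the model
#' constraint epsilon in (0, 1/2]:
#' epsilon_k = s*k/2 for k <= K/2, s*(K-k+1)/2 otherwise.
#'
#' @param K number of components (>= 2).
#' @param N number of genomes.
#' @param constrained shared dispersion per component (default TRUE).
#' @param epsFloor lower clamp on dispersion.
#' @return a \linkS4class{BMMParams}.
#' @export
triangularInit <- function(K, N, constrained = TRUE, epsFloor = 1e-4) {
  if (K < 2) stop("K must be >= 2")
  if (N < 1) stop("N must be >= 1")
  K <- as.integer(K)
  s <- 1 / ceiling(K / 2)
  k <- seq_len(K)
  lower <- k <= K / 2
  eps_k <- ifelse(lower, s * k / 2, s * (K - k + 1) / 2)
  # even K gives the two central components epsilon = 1/2 exactly, where
  # the Bernoulli density no longer depends on mu: the pair is
  # exchangeable and EM could never separate it. Deterministic tie-break:
  # lower the upper-central dispersion by s/4.
  if (K %% 2 == 0) eps_k[K / 2 + 1] <- eps_k[K / 2 + 1] - s / 4
  eps_k <- pmin(pmax(eps_k, epsFloor), 0.5)
  mu <- matrix(as.numeric(lower), nrow = K, ncol = N)
  epsilon <- matrix(eps_k, nrow = K, ncol = N)
  new("BMMParams", K = K, pi = rep(1 / K, K), mu = mu, epsilon = epsilon,
      constrained = constrained)
}

# F x K matrix of per-family Bernoulli log-densities.
# |x - mu| = x + mu - 2*x*mu, so the sum over genomes factorizes into a
# per-component constant plus a single matrix product with X.
logDensityMatrix <- function(X, params) {
  mu <- params@mu
  eps <- params@epsilon
  L1 <- log(eps)
  L0 <- log1p(-eps)
  A <- (L1 - L0) * (1 - 2 * mu)
  cst <- rowSums(mu * (L1 - L0) + L0)
  D <- as.matrix(X %*% t(A))
  sweep(D, 2L, cst, "+")
}

#' Log-density of one family's presence pattern under one component
#'
#' sum_j |x_j - mu_kj| log(eps_kj) + (1 - |x_j - mu_kj|) log(1 - eps_kj).
#'
#' @param x binary presence vector of length N.
#' @param k component index.
#' @param params a \linkS4class{BMMParams}.
#' @return log-density (scalar).
#' @export
familyLogDensity <- function(x, k, params) {
  d <- abs(x - params@mu[k, ])
  sum(d * log(params@epsilon[k, ]) + (1 - d) * log1p(-params@epsilon[k, ]))
}

rowLogSumExp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' E-step of the Bernoulli mixture EM
#'
#' Posterior responsibilities t_ik proportional to pi_k times the component
#' density, computed in log space with log-sum-exp normalization, plus the
#' observed-data log-likelihood.
#'
#' @param X a \linkS4class{PAMatrix} or binary matrix.
#' @param params a \linkS4class{BMMParams}.
#' @return list with \code{posterior} (F x K, rows sum to 1) and
#'   \code{loglik}.
#' @export
eStep <- function(X, params) {
  X <- paToDense(X)
  lp <- sweep(logDensityMatrix(X, params), 2L, log(params@pi), "+")
  lse <- rowLogSumExp(lp)
  T <- exp(lp - lse)
  dimnames(T) <- list(rownames(X), NULL)
  list(posterior = T, loglik = sum(lse))
}

#' M-step of the Bernoulli mixture EM
#'
#' Standard weighted updates: pi from mean responsibilities; mu_kj set to 1
#' when the responsibility-weighted presence exceeds 1/2 (ties to 0);
#' epsilon as the weighted mean mismatch rate, clamped to
#' [epsFloor, 1/2] and averaged over genomes per component in constrained
#' mode. A component whose total responsibility vanishes is re-seeded from
#' its triangular initialization with a warning.
#'
#' @param X a PAMatrix or binary matrix.
#' @param T F x K row-normalized posterior matrix.
#' @param constrained shared dispersion per component.
#' @param epsFloor lower clamp on dispersion.
#' @return a \linkS4class{BMMParams}.
#' @export
mStep <- function(X, T, constrained = TRUE, epsFloor = 1e-4) {
  X <- paToDense(X)
  F <- nrow(X)
  K <- ncol(T)
  N <- ncol(X)
  nk <- colSums(T)
  empty <- nk < 1e-8
  pi <- nk / F
  nk_safe <- pmax(nk, 1e-8)
  P <- (t(T) %*% X) / nk_safe          # K x N weighted presence frequency
  mu <- (P > 0.5) * 1                  # tie (exactly 0.5) -> 0
  eps <- mu + P - 2 * mu * P           # weighted mean |x - mu|
  if (constrained) eps <- matrix(rowMeans(eps), K, N)
  eps <- pmin(pmax(eps, epsFloor), 0.5)
  if (any(empty)) {
    warning("re-seeding ", sum(empty),
            " empty mixture component(s) from triangular initialization")
    init <- triangularInit(K, N, constrained, epsFloor)
    mu[empty, ] <- init@mu[empty, ]
    eps[empty, ] <- init@epsilon[empty, ]
    pi[empty] <- 1 / F
    pi <- pi / sum(pi)
  }
  new("BMMParams", K = as.integer(K), pi = as.numeric(pi), mu = mu,
      epsilon = eps, constrained = constrained)
}

# reorder components so component 1 has the highest mean presence
# probability and component K the lowest (guards against label drift;
# the triangular start makes this a no-op in the typical case)
sortComponentsByPresence <- function(params, T) {
  p <- params@mu * (1 - params@epsilon) + (1 - params@mu) * params@epsilon
  ord <- order(rowMeans(p), decreasing = TRUE)
  params@pi <- params@pi[ord]
  params@mu <- params@mu[ord, , drop = FALSE]
  params@epsilon <- params@epsilon[ord, , drop = FALSE]
  list(params = params, posterior = T[, ord, drop = FALSE])
}

paToDense <- function(X) {
  if (methods::is(X, "PAMatrix")) return(as.matrix(X@presence))
  as.matrix(X)
}

#' Fit the Bernoulli mixture by EM (BinEM)
#'
#' Alternates \code{\link{eStep}} and \code{\link{mStep}} from the
#' triangular initialization until the relative log-likelihood change drops
#' below \code{tol} or \code{maxIter} iterations. After convergence the
#' components are re-sorted by decreasing mean presence probability so that
#' component 1 is the persistent-like and component K the cloud-like one.
#'
#' @param X a \linkS4class{PAMatrix} or binary families x genomes matrix.
#' @param K number of components (2 <= K <= F).
#' @param maxIter maximum EM iterations (10 inside K selection).
#' @param tol relative log-likelihood convergence tolerance.
#' @param constrained shared dispersion per component (default TRUE).
#' @param epsFloor lower clamp on dispersion.
#' @return list with \code{params} (\linkS4class{BMMParams}),
#'   \code{posterior} (F x K), \code{loglik} (trace, one entry per
#'   iteration, non-decreasing).
#' @export
runBinEM <- function(X, K, maxIter = 100, tol = 1e-6, constrained = TRUE,
                     epsFloor = 1e-4) {
  Xd <- paToDense(X)
  if (K > nrow(Xd)) stop("K must not exceed the number of families")
  params <- triangularInit(K, ncol(Xd), constrained, epsFloor)
  trace <- numeric(0)
  es <- eStep(Xd, params)
  for (it in seq_len(maxIter)) {
    trace <- c(trace, es$loglik)
    params <- mStep(Xd, es$posterior, constrained, epsFloor)
    es2 <- eStep(Xd, params)
    if (abs(es2$loglik - es$loglik) <
        tol * max(1, abs(es$loglik))) {
      es <- es2
      trace <- c(trace, es$loglik)
      break
    }
    es <- es2
  }
  srt <- sortComponentsByPresence(params, es$posterior)
  list(params = srt$params, posterior = srt$posterior, loglik = trace)
}

#' Assign gene families to pangenome partitions
#'
#' A family goes to its maximum-posterior component when that posterior
#' exceeds 0.5 (strictly); component 1 is labeled persistent, component K
#' cloud, the rest shell. Otherwise the family is assigned to the shell,
#' recording its best shell component as sub-label.
#'
#' @param posterior F x K posterior matrix (rows sum to 1).
#' @param familyIds optional family ids (default rownames).
#' @return a \linkS4class{Partitioning}.
#' @export
assignPartitions <- function(posterior, familyIds = rownames(posterior)) {
  K <- ncol(posterior)
  F <- nrow(posterior)
  if (is.null(familyIds)) familyIds <- paste0("family_", seq_len(F))
  comp <- max.col(posterior, ties.method = "first")
  maxp <- posterior[cbind(seq_len(F), comp)]
  decided <- maxp > 0.5
  shell_cols <- setdiff(seq_len(K), c(1L, K))
  labelOf <- function(k) {
    ifelse(k == 1L, "persistent", ifelse(k == K, "cloud", "shell"))
  }
  labels <- labelOf(comp)
  if (any(!decided)) {
    if (length(shell_cols)) {
      sub <- posterior[, shell_cols, drop = FALSE]
      best_shell <- shell_cols[max.col(sub, ties.method = "first")]
      comp[!decided] <- best_shell[!decided]
    }
    labels[!decided] <- "shell"
  }
  sublabel <- labels
  if (K > 3) {
    is_shell <- labels == "shell"
    sublabel[is_shell] <- paste0("shell_", comp[is_shell])
  }
  new("Partitioning", familyIds = as.character(familyIds), labels = labels,
      component = as.integer(comp), sublabel = sublabel,
      posterior = posterior, K = as.integer(K))
}
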