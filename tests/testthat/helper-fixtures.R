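# shared fixture builders and independent oracles

# minimal gene table: one row per gene, positions spaced by 1000
makeGenes <- function(spec, circular = FALSE) {
  # spec: named list genome -> list(contig -> character vector of families)
  rows <- list()
  for (g in names(spec)) {
    for (ct in names(spec[[g]])) {
      fams <- spec[[g]][[ct]]
      n <- length(fams)
      rows[[paste(g, ct)]] <- data.frame(
        gene_id = paste0(g, "_", ct, "_", seq_len(n)), genome_id = g,
        contig_id = ct, start = (seq_len(n) - 1) * 1000 + 1,
        end = (seq_len(n) - 1) * 1000 + 900, strand = "+",
        family_id = fams, circular = circular,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# brute-force mixture posterior/log-likelihood: direct products of the
# printed Bernoulli mixture density, no log-space tricks
bruteForceMixture <- function(X, params) {
  F <- nrow(X); K <- params@K
  dens <- matrix(0, F, K)
  for (i in seq_len(F)) {
    for (k in seq_len(K)) {
      p <- params@pi[k]
      for (j in seq_len(ncol(X))) {
        d <- abs(X[i, j] - params@mu[k, j])
        e <- params@epsilon[k, j]
        p <- p * e^d * (1 - e)^(1 - d)
      }
      dens[i, k] <- p
    }
  }
  list(posterior = dens / rowSums(dens),
       loglik = sum(log(rowSums(dens))))
}

# random valid BMM parameters for oracle checks
randomParams <- function(K, N, constrained = FALSE) {
  pi <- stats::runif(K); pi <- pi / sum(pi)
  mu <- matrix(stats::rbinom(K * N, 1, 0.5), K, N)
  eps <- matrix(stats::runif(K * N, 0.05, 0.45), K, N)
  if (constrained) eps <- matrix(rowMeans(eps), K, N)
  new("BMMParams", K = as.integer(K), pi = pi, mu = mu, epsilon = eps,
      constrained = constrained)
}

randomPA <- function(F, N) {
  X <- matrix(stats::rbinom(F * N, 1, 0.5), F, N,
              dimnames = list(sprintf("f%03d", seq_len(F)),
                              sprintf("g%03d", seq_len(N))))
  X[rowSums(X) == 0, 1] <- 1
  X
}

# direct per-genome adjacency census, independent of the graph builder
censusAdjacencies <- function(genes) {
  genes <- validateGeneTable(genes)
  total <- 0L
  for (key in unique(paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    d <- genes[paste(genes$genome_id, genes$contig_id, sep = "\r") == key, ]
    m <- nrow(d)
    if (m >= 2) total <- total + (m - 1L) + as.integer(d$circular[1])
  }
  total
}
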