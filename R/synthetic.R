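#' Ground-truth mixture parameters for synthetic pangenomes
#'
#' Three-pattern truth (default): persistent families present everywhere
#' (mu = 1, eps = 0.05), one shell block present in the first half of the
#' genomes (eps = 0.3), cloud families rare (mu = 0, eps = 0.05), with
#' pi = (0.3, 0.2, 0.5). The four-pattern truth replaces the shell by two
#' antagonistic blocks (first-half and second-half centroids) with
#' pi = (0.3, 0.15, 0.15, 0.4) and eps = (0.05, 0.2, 0.2, 0.05).
#'
#' @param N number of genomes.
#' @param patterns 3 or 4 presence/absence patterns.
#' @param pi,eps optional overrides (length = patterns).
#' @return a \linkS4class{BMMParams} (constrained dispersion).
#' @export
truthParams <- function(N, patterns = 3, pi = NULL, eps = NULL) {
  if (!patterns %in% c(3, 4)) stop("patterns must be 3 or 4")
  half <- as.numeric(seq_len(N) <= N / 2)
  if (patterns == 3) {
    if (is.null(pi)) pi <- c(0.3, 0.2, 0.5)
    if (is.null(eps)) eps <- c(0.05, 0.3, 0.05)
    mu <- rbind(rep(1, N), half, rep(0, N))
  } else {
    if (is.null(pi)) pi <- c(0.3, 0.15, 0.15, 0.4)
    if (is.null(eps)) eps <- c(0.05, 0.2, 0.2, 0.05)
    mu <- rbind(rep(1, N), half, 1 - half, rep(0, N))
  }
  new("BMMParams", K = as.integer(patterns), pi = pi / sum(pi), mu = mu,
      epsilon = matrix(eps, patterns, N), constrained = TRUE)
}

componentLabels <- function(component, K) {
  ifelse(component == 1L, "persistent",
         ifelse(component == K, "cloud", "shell"))
}

drawPattern <- function(mu, eps, n) {
  flips <- matrix(stats::runif(n * length(mu)) < rep(eps, each = n),
                  nrow = n)
  mu_m <- matrix(mu, nrow = n, ncol = length(mu), byrow = TRUE)
  abs(mu_m - flips)
}

#' Generate a presence/absence matrix from the Bernoulli mixture
#'
#' Each family draws its component from pi, then its presence in genome j
#' is the component centroid mu_kj flipped independently with probability
#' eps_kj. Families drawn absent everywhere are redrawn so the matrix
#' respects the row-sum invariant; the number of redraws is attached as
#' attribute \code{redraws}.
#'
#' @param F number of gene families.
#' @param N number of genomes.
#' @param params true \linkS4class{BMMParams} (default
#'   \code{truthParams(N)}).
#' @param seed RNG seed.
#' @return list with \code{pa} (\linkS4class{PAMatrix}), \code{component}
#'   (true component per family) and \code{labels} (true
#'   persistent/shell/cloud labels).
#' @export
generatePA <- function(F, N, params = truthParams(N), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- params@K
  z <- sample.int(K, F, replace = TRUE, prob = params@pi)
  X <- matrix(0, F, N)
  for (k in seq_len(K)) {
    rows <- which(z == k)
    if (length(rows))
      X[rows, ] <- drawPattern(params@mu[k, ], params@epsilon[k, ],
                               length(rows))
  }
  redraws <- 0L
  repeat {
    zero <- which(rowSums(X) == 0)
    if (!length(zero) || redraws >= 100L) break
    for (i in zero)
      X[i, ] <- drawPattern(params@mu[z[i], ], params@epsilon[z[i], ], 1)
    redraws <- redraws + 1L
  }
  # pathological all-zero rows (possible at extreme eps): force one presence
  zero <- which(rowSums(X) == 0)
  if (length(zero)) X[cbind(zero, sample.int(N, length(zero), TRUE))] <- 1
  dimnames(X) <- list(sprintf("fam_%04d", seq_len(F)),
                      sprintf("genome_%04d", seq_len(N)))
  pa <- PAMatrix(X)
  attr(pa, "redraws") <- redraws
  list(pa = pa, component = stats::setNames(z, rownames(X)),
       labels = stats::setNames(componentLabels(z, K), rownames(X)))
}

# group accessory families into islands: runs of equal true component,
# chopped into blocks of at most islandSize
defaultIslands <- function(fams, component, islandSize) {
  if (!length(fams)) return(list())
  comp <- component[fams]
  run <- cumsum(c(TRUE, comp[-1] != comp[-length(comp)]))
  islands <- list()
  for (r in unique(run)) {
    members <- fams[run == r]
    blocks <- split(members, ceiling(seq_along(members) / islandSize))
    islands <- c(islands, unname(blocks))
  }
  islands
}

#' Lay generated families out into genomes with island hotspots
#'
#' Persistent families are placed on a fixed circular reference backbone
#' shared by all genomes; shell and cloud families are grouped into
#' islands, and each island is anchored at one of a few backbone hotspot
#' positions shared across genomes, emulating the preferential insertion
#' of transferred genes. Each genome carries its present families in
#' backbone/island order on one circular contig, rotated at a random
#' origin.
#'
#' @param pa a \linkS4class{PAMatrix} from \code{\link{generatePA}}.
#' @param component true component per family (1 = persistent).
#' @param hotspots number of insertion hotspots (default 5).
#' @param seed RNG seed (controls origins only).
#' @param islandSize maximum families per island.
#' @param islands optional explicit list of family-id vectors.
#' @param circular mark contigs circular (default TRUE).
#' @return a gene table (see \code{\link{validateGeneTable}}).
#' @export
generateGenomes <- function(pa, component, hotspots = 5, seed = NULL,
                            islandSize = 8, islands = NULL,
                            circular = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  fams <- familyNames(pa)
  comp <- component[fams]
  persistent <- fams[comp == 1L]
  if (!length(persistent)) stop("no persistent families to form a backbone")
  accessory <- fams[comp != 1L]
  if (is.null(islands))
    islands <- defaultIslands(accessory, component, islandSize)

  P <- length(persistent)
  key <- stats::setNames(numeric(length(fams)), fams)
  key[persistent] <- seq_len(P) * 1e9
  if (length(islands)) {
    h0 <- (seq_along(islands) - 1) %% hotspots
    anchors <- (round(h0 * P / hotspots) %% P) + 1
    for (m in seq_along(islands)) {
      mem <- islands[[m]]
      key[mem] <- anchors[m] * 1e9 + m * 1e4 + seq_along(mem)
    }
  }

  X <- as.matrix(pa@presence)
  gens <- genomeNames(pa)
  tabs <- vector("list", length(gens))
  for (j in seq_along(gens)) {
    present <- fams[X[, j] > 0]
    ord <- present[order(key[present])]
    L <- length(ord)
    if (L > 1) {
      r <- sample.int(L, 1)
      ord <- c(ord[r:L], ord[seq_len(r - 1)])
    }
    pos <- seq_len(L)
    tabs[[j]] <- data.frame(
      gene_id = paste0(gens[j], "_g", pos), genome_id = gens[j],
      contig_id = "contig_1", start = (pos - 1) * 1000 + 1,
      end = (pos - 1) * 1000 + 900, strand = "+", family_id = ord,
      circular = circular, stringsAsFactors = FALSE)
  }
  validateGeneTable(do.call(rbind, tabs))
}

#' Degrade genomes by assembly fragmentation and gene loss
#'
#' Removes each gene independently with probability \code{lossRate}, then
#' breaks each remaining contig junction (including the circular closure)
#' independently with probability \code{fragmentationRate}; broken circular
#' contigs become linear pieces. Adjacency lost in one genome can still be
#' contributed by intact genomes in the union graph.
#'
#' @param genes a gene table.
#' @param fragmentationRate junction break probability in [0, 1].
#' @param lossRate gene loss probability in [0, 1].
#' @param seed RNG seed.
#' @return a degraded gene table.
#' @export
degradeGenomes <- function(genes, fragmentationRate = 0, lossRate = 0,
                           seed = NULL) {
  if (fragmentationRate < 0 || fragmentationRate > 1 ||
      lossRate < 0 || lossRate > 1)
    stop("rates must lie in [0, 1]")
  genes <- validateGeneTable(genes)
  if (!is.null(seed)) set.seed(seed)
  if (lossRate > 0) {
    keep <- stats::runif(nrow(genes)) >= lossRate
    genes <- genes[keep, , drop = FALSE]
    if (!nrow(genes)) stop("all genes lost")
  }
  if (fragmentationRate == 0) return(validateGeneTable(genes))

  grp <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(genes)), grp), function(rows) {
    d <- genes[rows, , drop = FALSE]
    m <- nrow(d)
    circ <- d$circular[1]
    if (m == 1) return(d)
    nj <- if (circ) m else m - 1L
    broken <- stats::runif(nj) < fragmentationRate
    if (!any(broken)) return(d)
    if (circ) {
      # open the circle just after the first broken junction
      b1 <- which(broken)[1]
      rot <- c(seq_len(m)[-seq_len(b1)], seq_len(b1))
      d <- d[rot, , drop = FALSE]
      broken <- c(broken[-seq_len(b1)], broken[seq_len(b1)])[-m]
      d$circular <- FALSE
      d$start <- (seq_len(m) - 1) * 1000 + 1
      d$end <- d$start + 899
      m1 <- m - 1L
    } else {
      m1 <- m - 1L
      broken <- broken[seq_len(m1)]
    }
    piece <- cumsum(c(0L, as.integer(broken[seq_len(m1)]))) + 1L
    d$contig_id <- paste0(d$contig_id, ".", piece)
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  validateGeneTable(out)
}

#' Simulate a complete synthetic pangenome with known truth
#'
#' Draws family components and presence patterns from the ground-truth
#' mixture, with island families sharing correlated presence draws
#' (probability \code{rhoBlock} of copying a shared island draw) so that
#' graph neighborhoods carry label signal, then lays genomes out with
#' \code{\link{generateGenomes}}.
#'
#' @param F number of gene families (default 500).
#' @param N number of genomes (default 50).
#' @param patterns 3 or 4 (see \code{\link{truthParams}}).
#' @param params optional explicit true \linkS4class{BMMParams}.
#' @param hotspots insertion hotspots (default 5).
#' @param rhoBlock within-island presence correlation (default 0.8).
#' @param islandSize maximum families per island (default 8).
#' @param seed RNG seed.
#' @return list with \code{genes}, \code{pa}, \code{params},
#'   \code{component}, \code{labels} and \code{islands}.
#' @export
simulatePangenome <- function(F = 500, N = 50, patterns = 3, params = NULL,
                              hotspots = 5, rhoBlock = 0.8, islandSize = 8,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- truthParams(N, patterns)
  K <- params@K
  z <- sample.int(K, F, replace = TRUE, prob = params@pi)
  fams <- sprintf("fam_%04d", seq_len(F))
  names(z) <- fams
  islands <- defaultIslands(fams[z != 1L], z, islandSize)

  X <- matrix(0, F, N, dimnames = list(fams, sprintf("genome_%04d",
                                                     seq_len(N))))
  prows <- which(z == 1L)
  if (length(prows))
    X[prows, ] <- drawPattern(params@mu[1L, ], params@epsilon[1L, ],
                              length(prows))
  for (isl in islands) {
    k <- z[isl[1]]
    shared <- drawPattern(params@mu[k, ], params@epsilon[k, ], 1)[1, ]
    for (f in isl) {
      own <- drawPattern(params@mu[k, ], params@epsilon[k, ], 1)[1, ]
      copy <- stats::runif(N) < rhoBlock
      X[f, ] <- ifelse(copy, shared, own)
    }
  }
  zero <- which(rowSums(X) == 0)
  for (i in zero) {
    tries <- 0
    while (sum(X[i, ]) == 0 && tries < 100) {
      X[i, ] <- drawPattern(params@mu[z[i], ], params@epsilon[z[i], ], 1)
      tries <- tries + 1
    }
    if (sum(X[i, ]) == 0) X[i, sample.int(N, 1)] <- 1
  }
  pa <- PAMatrix(X)
  genes <- generateGenomes(pa, z, hotspots = hotspots,
                           islandSize = islandSize, islands = islands)
  list(genes = genes, pa = pa, params = params, component = z,
       labels = stats::setNames(componentLabels(z, K), fams),
       islands = islands)
}

#' Label agreement against a ground truth
#'
#' Fraction of families whose 3-way label (persistent/shell/cloud) matches
#' the truth.
#'
#' @param partitioning a \linkS4class{Partitioning}.
#' @param trueLabels named character vector of true labels.
#' @return accuracy in [0, 1].
#' @export
labelAccuracy <- function(partitioning, trueLabels) {
  lab <- partitionLabels(partitioning)
  common <- intersect(names(lab), names(trueLabels))
  mean(lab[common] == trueLabels[common])
}
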