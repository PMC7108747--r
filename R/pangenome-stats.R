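#' Per-partition graph topology statistics
#'
#' For each partition label, induces the subgraph on same-label families
#' (self-loops excluded) and reports the mean within-partition degree plus
#' a connected-component census. Cross-partition degrees (edges leaving the
#' partition) are reported separately for transparency.
#'
#' @param graph a \linkS4class{PangenomeGraph}.
#' @param partitioning a \linkS4class{Partitioning} over the graph's
#'   families.
#' @return data.frame with one row per label: \code{n_nodes},
#'   \code{mean_degree} (intra-partition), \code{mean_cross_degree},
#'   \code{n_components}, \code{largest_component}, \code{singletons}.
#' @export
partitionDegreeStats <- function(graph, partitioning) {
  lab <- partitionLabels(partitioning)
  g <- asIgraph(graph)
  labs <- c("persistent", "shell", "cloud")
  out <- lapply(labs, function(L) {
    nodes <- names(lab)[lab == L]
    nodes <- intersect(nodes, igraph::V(g)$name)
    if (!length(nodes))
      return(data.frame(label = L, n_nodes = 0L, mean_degree = NA_real_,
                        mean_cross_degree = NA_real_,
                        n_components = NA_integer_,
                        largest_component = NA_integer_,
                        singletons = NA_integer_))
    sg <- igraph::induced_subgraph(g, nodes)
    full_deg <- igraph::degree(g, v = nodes)
    intra_deg <- igraph::degree(sg)
    comp <- igraph::components(sg)
    data.frame(label = L, n_nodes = length(nodes),
               mean_degree = mean(intra_deg),
               mean_cross_degree = mean(full_deg - intra_deg),
               n_components = comp$no,
               largest_component = max(comp$csize),
               singletons = sum(comp$csize == 1))
  })
  do.call(rbind, out)
}

#' Jaccard distances between genomes on a binary family matrix
#'
#' d(a, b) = 1 - |intersection| / |union| over presence sets; two genomes
#' with empty union get distance 0.
#'
#' @param M genomes x families binary matrix.
#' @return symmetric N x N distance matrix.
#' @export
jaccardDistances <- function(M) {
  M <- as.matrix(M) * 1
  inter <- M %*% t(M)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  d <- ifelse(uni > 0, 1 - inter / uni, 0)
  diag(d) <- 0
  d
}

#' Correlation of shell composition with genomic distances
#'
#' Computes the Jaccard distance between every genome pair on the
#' presence/absence vectors of shell families and correlates (Spearman) the
#' upper triangle with a user-supplied genomic distance matrix (e.g. Mash
#' distances); a strong correlation indicates that shell composition
#' tracks phylogenetic structure.
#'
#' @param X a \linkS4class{PAMatrix}.
#' @param partitioning a \linkS4class{Partitioning}.
#' @param genomeDistances symmetric N x N matrix with zero diagonal, rows
#'   and columns named by genome ids.
#' @return list with \code{rho}, \code{p.value} and the shell
#'   \code{jaccard} matrix.
#' @export
shellStructureCorrelation <- function(X, partitioning, genomeDistances) {
  gens <- genomeNames(X)
  if (length(gens) < 3) stop("need at least 3 genomes")
  D <- as.matrix(genomeDistances)
  if (!all(gens %in% rownames(D)))
    stop("distance matrix must cover all genomes")
  D <- D[gens, gens]
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-8))
    stop("distance matrix must be symmetric with zero diagonal")
  lab <- partitionLabels(partitioning)
  shell <- names(lab)[lab == "shell"]
  shell <- intersect(shell, familyNames(X))
  if (!length(shell)) stop("no shell families to correlate")
  M <- t(as.matrix(X@presence[shell, , drop = FALSE]))
  J <- jaccardDistances(M)
  ut <- upper.tri(J)
  ct <- suppressWarnings(
    stats::cor.test(J[ut], D[ut], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, jaccard = J)
}

#' Per-genome partition content summary
#'
#' Counts, for every genome, the persistent/shell/cloud families it
#' carries, with medians and interquartile ranges across genomes, plus the
#' soft-core size at the given threshold.
#'
#' @param partitioning a \linkS4class{Partitioning}.
#' @param X a \linkS4class{PAMatrix}.
#' @param softThreshold soft-core presence fraction (default 0.95).
#' @return list with \code{perGenome} (data.frame genome x counts),
#'   \code{medians}, \code{iqr} (named vectors) and \code{softCore}.
#' @export
summaryTable <- function(partitioning, X, softThreshold = 0.95) {
  lab <- partitionLabels(partitioning)[familyNames(X)]
  P <- X@presence
  perLab <- vapply(c("persistent", "shell", "cloud"), function(L) {
    rows <- which(lab == L)
    if (!length(rows)) return(numeric(ncol(P)))
    as.numeric(Matrix::colSums(P[rows, , drop = FALSE]))
  }, numeric(ncol(P)))
  perGenome <- data.frame(genome_id = genomeNames(X), perLab,
                          total = as.numeric(Matrix::colSums(P)))
  occ <- Matrix::rowSums(P)
  softCore <- sum(occ >= ceiling(softThreshold * ncol(P)))
  med <- apply(perLab, 2, stats::median)
  iqr <- apply(perLab, 2, stats::IQR)
  list(perGenome = perGenome, medians = med, iqr = iqr,
       softCore = softCore)
}

#' Convert a Mash distance to its ANI equivalent
#'
#' Average Nucleotide Identity (percent) corresponding to a Mash genomic
#' distance: 100 * (1 - d). The usual conspecific cutoff d = 0.06
#' corresponds to 94% ANI.
#'
#' @param d Mash distance in [0, 1].
#' @return ANI percentage.
#' @export
mashToANI <- function(d) {
  if (any(d < 0 | d > 1)) stop("Mash distances must lie in [0, 1]")
  100 * (1 - d)
}
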