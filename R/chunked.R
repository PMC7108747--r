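#' Randomly split genomes into chunks
#'
#' Shuffles the genome ids and cuts them into chunks of \code{chunkSize};
#' when the last chunk would hold fewer than \code{chunkSize/2} genomes it
#' is merged into the previous one (set \code{mergeLast = FALSE} to keep
#' it). With N <= chunkSize a single chunk holds every genome.
#'
#' @param genomeIds character vector of genome ids.
#' @param chunkSize target chunk size (>= 2; at least 500 advised for
#'   representative chunks on real data).
#' @param seed RNG seed for the shuffle.
#' @param mergeLast merge an undersized trailing chunk.
#' @return list of character vectors.
#' @export
makeChunks <- function(genomeIds, chunkSize = 500, seed = NULL,
                       mergeLast = TRUE) {
  if (chunkSize < 2) stop("chunkSize must be >= 2")
  n <- length(genomeIds)
  if (n <= chunkSize) return(list(genomeIds))
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(genomeIds)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunkSize))
  chunks <- lapply(idx, function(i) ids[i])
  last <- length(chunks)
  if (mergeLast && last > 1 && length(chunks[[last]]) < chunkSize / 2) {
    chunks[[last - 1]] <- c(chunks[[last - 1]], chunks[[last]])
    chunks[[last]] <- NULL
  }
  unname(chunks)
}

#' Chunked pangenome partitioning with absolute-majority voting
#'
#' Scales partitioning to large cohorts: each round randomly splits the
#' genomes into chunks, partitions every chunk independently (P/A columns
#' and induced graph restricted to the chunk, weights recomputed with the
#' chunk's N), and records each family's label in every chunk where it is
#' present. A family is decided once a unique modal label holds at least
#' half of the samplings in which the family was present (absolute
#' majority); undecided families trigger further rounds of re-sampling.
#' Families still undecided after \code{maxRounds} fall back to the shell
#' with a warning, consistent with the assign-to-shell-when-uncertain rule.
#' Shell sub-labels are collapsed to "shell" for voting.
#'
#' With N <= chunkSize the single chunk makes this identical to
#' \code{\link{runNEM}} on the full data.
#'
#' @param X a \linkS4class{PAMatrix}.
#' @param graph a \linkS4class{PangenomeGraph} (NULL for matrix-only mode).
#' @param K number of partitions, fixed in advance (e.g. from
#'   \code{\link{selectK}}).
#' @param beta,maxDegree,constrained NEM controls (see \code{\link{runNEM}}).
#' @param chunkSize genomes per chunk (default 500).
#' @param maxRounds sampling rounds before the shell fallback.
#' @param seed RNG seed controlling the chunk shuffles.
#' @return a \linkS4class{Partitioning} (no posterior; consensus labels).
#' @export
partitionChunked <- function(X, graph, K, beta = 2.5, maxDegree = 10,
                             constrained = TRUE, chunkSize = 500,
                             maxRounds = 10, seed = NULL) {
  fams <- familyNames(X)
  gens <- genomeNames(X)
  lab_levels <- c("persistent", "shell", "cloud")
  votes <- matrix(0L, length(fams), 3, dimnames = list(fams, lab_levels))
  present <- stats::setNames(integer(length(fams)), fams)
  decided <- stats::setNames(rep(FALSE, length(fams)), fams)
  final <- stats::setNames(rep(NA_character_, length(fams)), fams)
  if (!is.null(seed)) set.seed(seed)

  for (round in seq_len(maxRounds)) {
    chunks <- makeChunks(gens, chunkSize)
    for (ch in chunks) {
      Xc <- X[, ch]
      cf <- familyNames(Xc)       # families present in this chunk
      grc <- if (!is.null(graph))
        subsetGraphGenomes(graph, ch, keepFamilies = cf) else NULL
      fit <- runNEM(Xc, grc, K = K, beta = beta, maxDegree = maxDegree,
                    constrained = constrained)
      lab <- partitionLabels(fit$partitioning)
      votes[cf, ] <- votes[cf, , drop = FALSE] +
        outer(lab, lab_levels, "==") * 1L
      present[cf] <- present[cf] + 1L
    }
    vmax <- apply(votes, 1L, max)
    unique_mode <- rowSums(votes == vmax) == 1L
    newly <- !decided & present > 0 & unique_mode &
      vmax >= 0.5 * present
    if (any(newly)) {
      final[newly] <- lab_levels[max.col(votes[newly, , drop = FALSE],
                                         ties.method = "first")]
      decided[newly] <- TRUE
    }
    if (all(decided)) break
  }
  if (!all(decided)) {
    warning(sum(!decided), " gene families undecided after ", maxRounds,
            " rounds; assigned to shell")
    final[!decided] <- "shell"
  }
  comp <- match(final, lab_levels)
  new("Partitioning", familyIds = fams, labels = unname(final),
      component = as.integer(ifelse(final == "cloud", K, comp)),
      sublabel = unname(final), posterior = NULL, K = as.integer(K))
}
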