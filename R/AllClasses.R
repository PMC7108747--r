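#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' PAMatrix: binary gene-family presence/absence matrix
#'
#' An F x N binary matrix with gene families as rows and genomes as columns.
#' An entry is 1 when the family has at least one member gene in the genome.
#' Stored sparsely; every row has at least one presence.
#'
#' @slot presence a \code{\link[Matrix]{dgCMatrix-class}} of 0/1 values with
#'   family ids as rownames and genome ids as colnames.
#' @export
setClass("PAMatrix", representation(presence = "dgCMatrix"))

setValidity("PAMatrix", function(object) {
  m <- object@presence
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("presence matrix must have family and genome dimnames")
  if (anyDuplicated(rownames(m))) return("duplicated family ids")
  if (anyDuplicated(colnames(m))) return("duplicated genome ids")
  if (length(m@x) && !all(m@x %in% c(0, 1)))
    return("presence values must be 0/1")
  if (any(Matrix::rowSums(m) < 1))
    return("every family must be present in at least one genome")
  TRUE
})

#' Construct a PAMatrix from a binary matrix
#'
#' @param mat a binary matrix (base or Matrix) with family rownames and
#'   genome colnames.
#' @return a \linkS4class{PAMatrix}.
#' @export
PAMatrix <- function(mat) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m)
  new("PAMatrix", presence = m)
}

#' PangenomeGraph: gene-family contiguity graph
#'
#' Nodes are gene families; an edge joins two families whenever a pair of
#' their genes is adjacent on some contig. Each edge records per-genome
#' adjacency counts; its weight is the total count divided by the number of
#' genomes, so weights can exceed 1 when paralogous adjacencies repeat
#' within genomes.
#'
#' @slot nodes data.frame with columns \code{family_id}, \code{gene_count}.
#' @slot edges data.frame with columns \code{from}, \code{to} (family ids,
#'   \code{from <= to}), \code{count}, \code{weight}, \code{self_loop}.
#' @slot edgeGenomeCounts sparse edges x genomes count matrix.
#' @slot nGenomes number of genomes N used for weighting.
#' @export
setClass("PangenomeGraph", representation(
  nodes = "data.frame",
  edges = "data.frame",
  edgeGenomeCounts = "dgCMatrix",
  nGenomes = "integer"
))

setValidity("PangenomeGraph", function(object) {
  e <- object@edges
  if (nrow(e) != nrow(object@edgeGenomeCounts))
    return("edge table and per-genome count matrix disagree")
  if (nrow(e)) {
    tot <- as.numeric(Matrix::rowSums(object@edgeGenomeCounts))
    if (any(abs(e$count - tot) > 1e-9))
      return("edge counts must equal per-genome count row sums")
    if (any(abs(e$weight - e$count / object@nGenomes) > 1e-9))
      return("edge weights must equal count / N")
    if (!all(c(e$from, e$to) %in% object@nodes$family_id))
      return("edge endpoints must be graph nodes")
  }
  TRUE
})

#' BMMParams: parameters of the multivariate Bernoulli mixture
#'
#' Theta = (pi, mu, epsilon) for K components over N genomes. mu is the
#' binary centroid of presence/absence per component, epsilon the dispersion
#' around it, constrained to [epsilon_floor, 1/2]. In constrained mode
#' (default) epsilon is identical across genomes within a component.
#'
#' @slot K number of components.
#' @slot pi mixing proportions, summing to 1.
#' @slot mu K x N binary centroid matrix.
#' @slot epsilon K x N dispersion matrix in (0, 1/2].
#' @slot constrained logical; shared dispersion per component.
#' @export
setClass("BMMParams", representation(
  K = "integer", pi = "numeric", mu = "matrix",
  epsilon = "matrix", constrained = "logical"
))

setValidity("BMMParams", function(object) {
  K <- object@K
  if (length(object@pi) != K) return("pi must have length K")
  if (abs(sum(object@pi) - 1) > 1e-8) return("pi must sum to 1")
  if (any(object@pi < -1e-12)) return("pi must be non-negative")
  if (nrow(object@mu) != K || nrow(object@epsilon) != K)
    return("mu and epsilon must have K rows")
  if (ncol(object@mu) != ncol(object@epsilon))
    return("mu and epsilon must have the same number of columns")
  if (!all(object@mu %in% c(0, 1))) return("mu must be binary")
  if (any(object@epsilon <= 0) || any(object@epsilon > 0.5 + 1e-12))
    return("epsilon must lie in (0, 1/2]")
  TRUE
})

#' Partitioning: per-family partition labels and posteriors
#'
#' @slot familyIds gene-family ids, in matrix row order.
#' @slot labels one of persistent/shell/cloud per family.
#' @slot component assigned mixture component index (1 = persistent,
#'   K = cloud).
#' @slot sublabel fine label; shell components are distinguished as
#'   \code{shell_2}, ..., \code{shell_(K-1)} when K > 3.
#' @slot posterior F x K posterior matrix (may be empty, e.g. after a
#'   chunked consensus).
#' @slot K number of mixture components behind the labels.
#' @export
setClass("Partitioning", representation(
  familyIds = "character", labels = "character", component = "integer",
  sublabel = "character", posterior = "matrixOrNULL", K = "integer"
))

setValidity("Partitioning", function(object) {
  F <- length(object@familyIds)
  if (length(object@labels) != F || length(object@component) != F ||
      length(object@sublabel) != F)
    return("labels, component and sublabel must match familyIds in length")
  if (!all(object@labels %in% c("persistent", "shell", "cloud")))
    return("labels must be persistent/shell/cloud")
  if (!is.null(object@posterior) && nrow(object@posterior) != F)
    return("posterior must have one row per family")
  TRUE
})

#' KSelection: ICL-based selection of the number of partitions
#'
#' @slot grid candidate K values.
#' @slot loglik,bic,icl,entropy criteria per candidate K.
#' @slot KHat selected number of partitions.
#' @slot deltaICL margin used for the parsimonious choice.
#' @export
setClass("KSelection", representation(
  grid = "integer", loglik = "numeric", bic = "numeric", icl = "numeric",
  entropy = "numeric", KHat = "integer", deltaICL = "numeric"
))

#' RarefactionResult: resampled pangenome component curves
#'
#' @slot samples data.frame (component, n, rep, count) of raw replicate
#'   counts.
#' @slot quartiles data.frame (component, n, q1, median, q3).
#' @slot heaps data.frame of Heaps' law fits (component, kappa, gamma,
#'   se_kappa, se_gamma, converged).
#' @slot iqrArea named numeric of interquartile ribbon areas per component.
#' @slot reps replicates per subset size.
#' @slot maxN largest subset size sampled.
#' @export
setClass("RarefactionResult", representation(
  samples = "data.frame", quartiles = "data.frame", heaps = "data.frame",
  iqrArea = "numeric", reps = "integer", maxN = "integer"
))
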