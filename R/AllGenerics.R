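#' @importClassesFrom Matrix dgCMatrix
NULL

#' Family identifiers
#' @param x a PAMatrix, PangenomeGraph or Partitioning.
#' @return character vector of gene-family ids.
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))

#' Genome identifiers
#' @param x a PAMatrix or PangenomeGraph.
#' @return character vector of genome ids.
#' @export
setGeneric("genomeNames", function(x) standardGeneric("genomeNames"))

#' Partition labels
#' @param x a Partitioning.
#' @return named character vector (persistent/shell/cloud) per family.
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' Posterior membership probabilities
#' @param x a Partitioning.
#' @return F x K posterior matrix, or NULL for consensus partitionings.
#' @export
setGeneric("posteriorMatrix", function(x) standardGeneric("posteriorMatrix"))

#' Edge table of a pangenome graph
#' @param x a PangenomeGraph.
#' @return data.frame of edges with counts and weights.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname familyNames
#' @export
setMethod("familyNames", "PAMatrix", function(x) rownames(x@presence))
#' @rdname familyNames
#' @export
setMethod("familyNames", "PangenomeGraph", function(x) x@nodes$family_id)
#' @rdname familyNames
#' @export
setMethod("familyNames", "Partitioning", function(x) x@familyIds)

#' @rdname genomeNames
#' @export
setMethod("genomeNames", "PAMatrix", function(x) colnames(x@presence))
#' @rdname genomeNames
#' @export
setMethod("genomeNames", "PangenomeGraph",
          function(x) colnames(x@edgeGenomeCounts))

#' @rdname partitionLabels
#' @export
setMethod("partitionLabels", "Partitioning", function(x) {
  stats::setNames(x@labels, x@familyIds)
})

#' @rdname posteriorMatrix
#' @export
setMethod("posteriorMatrix", "Partitioning", function(x) x@posterior)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "PangenomeGraph", function(x) x@edges)

#' @describeIn PAMatrix dimensions (families, genomes).
#' @param x a PAMatrix.
#' @export
setMethod("dim", "PAMatrix", function(x) dim(x@presence))

#' Dense base-matrix view of a PAMatrix
#' @param x a PAMatrix.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "PAMatrix", function(x, ...) {
  as.matrix(x@presence)
})

#' Subset a PAMatrix by families and/or genomes
#'
#' Families left with zero presence after genome subsetting are dropped,
#' preserving the row-sum invariant.
#' @param x a PAMatrix.
#' @param i,j family / genome indices or names.
#' @param ... ignored.
#' @param drop ignored (always returns a PAMatrix).
#' @export
setMethod("[", "PAMatrix", function(x, i, j, ..., drop = FALSE) {
  m <- x@presence
  if (!missing(i)) m <- m[i, , drop = FALSE]
  if (!missing(j)) m <- m[, j, drop = FALSE]
  m <- m[Matrix::rowSums(m) > 0, , drop = FALSE]
  new("PAMatrix", presence = m)
})

setMethod("show", "PAMatrix", function(object) {
  d <- dim(object@presence)
  cat("PAMatrix:", d[1], "gene families x", d[2], "genomes\n")
  occ <- Matrix::rowSums(object@presence)
  cat("  presence fill:",
      sprintf("%.1f%%", 100 * sum(occ) / prod(d)),
      "| families in all genomes:", sum(occ == d[2]), "\n")
})

setMethod("show", "PangenomeGraph", function(object) {
  cat("PangenomeGraph:", nrow(object@nodes), "families,",
      nrow(object@edges), "edges over", object@nGenomes, "genomes\n")
  if (nrow(object@edges))
    cat("  weight range:",
        sprintf("[%.3g, %.3g]", min(object@edges$weight),
                max(object@edges$weight)),
        "| self-loops:", sum(object@edges$self_loop), "\n")
})

setMethod("show", "BMMParams", function(object) {
  cat("BMMParams: K =", object@K, "components over",
      ncol(object@mu), "genomes",
      if (object@constrained) "(constrained dispersion)\n" else
        "(free dispersion)\n")
  cat("  pi:", paste(sprintf("%.3f", object@pi), collapse = " "), "\n")
  cat("  epsilon (per-component mean):",
      paste(sprintf("%.3f", rowMeans(object@epsilon)), collapse = " "), "\n")
})

setMethod("show", "Partitioning", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("persistent", "shell", "cloud")))
  cat("Partitioning of", length(object@familyIds), "gene families (K =",
      object@K, ")\n")
  cat(sprintf("  persistent: %d | shell: %d | cloud: %d\n",
              tab[["persistent"]], tab[["shell"]], tab[["cloud"]]))
})

setMethod("show", "KSelection", function(object) {
  cat("KSelection over K in", paste(range(object@grid), collapse = ".."),
      "-> K_hat =", object@KHat,
      sprintf("(delta_ICL = %.4g)\n", object@deltaICL))
})

setMethod("show", "RarefactionResult", function(object) {
  cat("RarefactionResult:", object@reps, "replicates per size, sizes up to",
      object@maxN, "\n")
  if (nrow(object@heaps)) {
    cat("  Heaps' law gamma:\n")
    for (r in seq_len(nrow(object@heaps)))
      cat(sprintf("    %-15s %.4f\n", object@heaps$component[r],
                  object@heaps$gamma[r]))
  }
})
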