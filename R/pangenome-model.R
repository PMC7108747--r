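#' @importFrom data.table data.table setkey := .N .SD
NULL

GENE_COLUMNS <- c("gene_id", "genome_id", "contig_id", "start", "end",
                  "strand", "family_id")

#' Validate and order a gene table
#'
#' A gene table is a data.frame with one row per gene and columns
#' \code{gene_id}, \code{genome_id}, \code{contig_id}, \code{start},
#' \code{end}, \code{strand}, \code{family_id} and optionally a logical
#' \code{circular} flag per contig (default FALSE). Coordinates are 1-based
#' inclusive as in GFF3. Genes are ordered within a contig by start,
#' ties broken by end then gene_id.
#'
#' @param genes data.frame of genes.
#' @return the validated gene table, ordered by (genome, contig, start).
#' @export
validateGeneTable <- function(genes) {
  genes <- as.data.frame(genes)
  missing_cols <- setdiff(GENE_COLUMNS, names(genes))
  if (length(missing_cols))
    stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!nrow(genes)) stop("gene table is empty")
  if (!"circular" %in% names(genes)) genes$circular <- FALSE
  if (anyNA(genes[GENE_COLUMNS]))
    stop("gene table contains missing values")
  if (any(genes$start < 1)) stop("gene starts must be >= 1 (1-based)")
  if (any(genes$end < genes$start)) stop("gene end must be >= start")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  dup <- duplicated(genes[c("genome_id", "gene_id")])
  if (any(dup))
    stop("duplicate gene_id within a genome: ",
         paste(unique(genes$gene_id[dup]), collapse = ", "))
  ord <- order(match(genes$genome_id, unique(genes$genome_id)),
               genes$contig_id, genes$start, genes$end, genes$gene_id)
  genes[ord, , drop = FALSE]
}

#' Read per-genome GFF3 annotations into a gene table
#'
#' One GFF3 file per genome; CDS records (and RNA gene records, if present)
#' are retained and mapped to gene families via \code{familyMap}. Gene ids
#' are taken from the ID attribute.
#'
#' @param paths character vector of GFF3 paths; names (or file basenames)
#'   become genome ids.
#' @param familyMap data.frame with columns \code{gene_id},
#'   \code{family_id}, e.g. from \code{\link{readFamilyMap}}.
#' @param types feature types to retain.
#' @return a validated gene table (see \code{\link{validateGeneTable}}).
#' @export
readGff3 <- function(paths, familyMap,
                     types = c("CDS", "tRNA", "rRNA", "tmRNA")) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.gff3?(\\.gz)?$", "", basename(paths))
  tabs <- lapply(names(paths), function(g) {
    gr <- as.data.frame(rtracklayer::import(paths[[g]]))
    gr <- gr[as.character(gr$type) %in% types, , drop = FALSE]
    if (!nrow(gr)) stop("no retained features in ", paths[[g]])
    id <- as.character(gr$ID)
    if (anyNA(id) || any(id == ""))
      stop("GFF3 features without ID attribute in ", paths[[g]])
    data.frame(gene_id = id, genome_id = g,
               contig_id = as.character(gr$seqnames),
               start = gr$start,
               end = gr$end,
               strand = ifelse(as.character(gr$strand) == "-", "-", "+"),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, tabs)
  fam <- familyMap$family_id[match(genes$gene_id, familyMap$gene_id)]
  if (anyNA(fam))
    stop("genes without family mapping: ",
         paste(utils::head(genes$gene_id[is.na(fam)], 20), collapse = ", "))
  genes$family_id <- fam
  validateGeneTable(genes)
}

#' Read a gene -> family mapping TSV
#'
#' Two tab-separated columns: gene_id, family_id. No header expected; a
#' header line is detected and skipped when its first field is "gene_id".
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{gene_id}, \code{family_id}.
#' @export
readFamilyMap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "family_id"),
                           colClasses = "character", quote = "")
  if (nrow(tab) && tab$gene_id[1] == "gene_id") tab <- tab[-1, ]
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene ids in family map")
  tab
}

#' Build the presence/absence matrix from a gene table
#'
#' An entry x_ij is 1 iff family i has at least one member gene in genome j.
#' Families are ordered by first appearance in the input, genomes by input
#' order.
#'
#' @param genes a gene table (validated if needed).
#' @return a \linkS4class{PAMatrix}.
#' @export
buildPAMatrix <- function(genes) {
  if (!nrow(as.data.frame(genes))) stop("empty genome set")
  fams <- unique(genes$family_id)
  gens <- unique(genes$genome_id)
  i <- match(genes$family_id, fams)
  j <- match(genes$genome_id, gens)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(fams), length(gens)),
                            dimnames = list(fams, gens), use.last.ij = TRUE)
  m@x[] <- 1
  new("PAMatrix", presence = Matrix::drop0(m))
}

#' Build the pangenome graph from a gene table
#'
#' Every pair of genes consecutive on a contig (plus the last-first pair of
#' circular contigs with >= 2 genes) contributes one adjacency between its
#' two families, counted per genome. Edge weight is total adjacency count
#' divided by N. Adjacent paralogs of one family give a flagged self-loop.
#' Strand is ignored: adjacency is positional only.
#'
#' @param genes a gene table.
#' @param nGenomes number of genomes N for the weight denominator; defaults
#'   to the number of distinct genomes in \code{genes}.
#' @return a \linkS4class{PangenomeGraph}.
#' @export
buildPangenomeGraph <- function(genes, nGenomes = NULL) {
  genes <- validateGeneTable(genes)
  gens <- unique(genes$genome_id)
  if (is.null(nGenomes)) nGenomes <- length(gens)
  nGenomes <- as.integer(nGenomes)

  dt <- data.table::as.data.table(genes)
  # consecutive in-contig pairs
  adj <- dt[, if (.N >= 2) list(
    f1 = family_id[-.N], f2 = family_id[-1]
  ), by = list(genome_id, contig_id)]
  # circular closures (wrap last -> first) for contigs with >= 2 genes
  wrap <- dt[, if (.N >= 2 && circular[1]) list(
    f1 = family_id[.N], f2 = family_id[1]
  ), by = list(genome_id, contig_id)]
  # an empty by-group result carries only the grouping columns
  plist <- Filter(nrow, list(adj, wrap))
  pairs <- if (length(plist)) data.table::rbindlist(plist) else adj

  node_counts <- dt[, list(gene_count = .N), by = family_id]
  nodes <- data.frame(family_id = unique(genes$family_id),
                      stringsAsFactors = FALSE)
  nodes$gene_count <- node_counts$gene_count[
    match(nodes$family_id, node_counts$family_id)]

  if (!nrow(pairs)) {
    edges <- data.frame(from = character(), to = character(),
                        count = numeric(), weight = numeric(),
                        self_loop = logical(), stringsAsFactors = FALSE)
    egc <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(0L, length(gens)),
                                dimnames = list(NULL, gens))
    return(new("PangenomeGraph", nodes = nodes, edges = edges,
               edgeGenomeCounts = egc, nGenomes = nGenomes))
  }

  pairs[, `:=`(from = pmin(f1, f2), to = pmax(f1, f2))]
  tal <- pairs[, list(n = .N), by = list(from, to, genome_id)]
  ekey <- paste(tal$from, tal$to, sep = "\r")
  ukey <- sort(unique(ekey))
  ei <- match(ekey, ukey)
  gj <- match(tal$genome_id, gens)
  egc <- Matrix::sparseMatrix(i = ei, j = gj, x = as.numeric(tal$n),
                              dims = c(length(ukey), length(gens)),
                              dimnames = list(NULL, gens))
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  count <- as.numeric(Matrix::rowSums(egc))
  edges <- data.frame(from = parts[, 1], to = parts[, 2],
                      count = count, weight = count / nGenomes,
                      self_loop = parts[, 1] == parts[, 2],
                      stringsAsFactors = FALSE)
  new("PangenomeGraph", nodes = nodes, edges = edges,
      edgeGenomeCounts = egc, nGenomes = nGenomes)
}

#' Node degrees in the pangenome graph
#'
#' Degree counted over non-self-loop edges of the full graph.
#' @param graph a PangenomeGraph.
#' @return named integer vector over all nodes.
#' @export
nodeDegrees <- function(graph) {
  deg <- stats::setNames(integer(nrow(graph@nodes)), graph@nodes$family_id)
  e <- graph@edges[!graph@edges$self_loop, , drop = FALSE]
  if (nrow(e)) {
    tab <- table(c(e$from, e$to))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Edges eligible for MRF smoothing
#'
#' Returns the non-self-loop edges whose two endpoints both have degree at
#' most \code{maxDegree} in the full graph. Hub families (typically mobile
#' elements) above the cap keep their labels but do not smooth neighbours.
#'
#' @param graph a PangenomeGraph.
#' @param maxDegree degree cap (default 10).
#' @return data.frame subset of the edge table.
#' @export
mrfEdges <- function(graph, maxDegree = 10) {
  if (maxDegree < 0) stop("maxDegree must be >= 0")
  e <- graph@edges[!graph@edges$self_loop, , drop = FALSE]
  if (!nrow(e)) return(e)
  deg <- nodeDegrees(graph)
  keep <- deg[e$from] <= maxDegree & deg[e$to] <= maxDegree
  e[keep, , drop = FALSE]
}

#' Restrict a pangenome graph to a genome subset
#'
#' Per-genome adjacency counts are restricted to the subset, zero-count
#' edges dropped, and weights recomputed with the subset size as N. Nodes
#' are restricted to families retained in \code{keepFamilies} when given.
#'
#' @param graph a PangenomeGraph.
#' @param genomes genome ids to keep.
#' @param keepFamilies optional family ids to keep as nodes.
#' @return a \linkS4class{PangenomeGraph}.
#' @export
subsetGraphGenomes <- function(graph, genomes, keepFamilies = NULL) {
  gens <- colnames(graph@edgeGenomeCounts)
  if (!all(genomes %in% gens)) stop("unknown genome ids")
  egc <- graph@edgeGenomeCounts[, genomes, drop = FALSE]
  count <- as.numeric(Matrix::rowSums(egc))
  keep <- count > 0
  edges <- graph@edges[keep, , drop = FALSE]
  egc <- egc[keep, , drop = FALSE]
  nodes <- graph@nodes
  if (!is.null(keepFamilies)) {
    nodes <- nodes[nodes$family_id %in% keepFamilies, , drop = FALSE]
    ek <- edges$from %in% nodes$family_id & edges$to %in% nodes$family_id
    edges <- edges[ek, , drop = FALSE]
    egc <- egc[ek, , drop = FALSE]
  }
  n <- length(genomes)
  edges$count <- as.numeric(Matrix::rowSums(egc))
  edges$weight <- edges$count / n
  rownames(edges) <- NULL
  new("PangenomeGraph", nodes = nodes, edges = edges,
      edgeGenomeCounts = egc, nGenomes = as.integer(n))
}

#' Convert a PangenomeGraph to an igraph object
#'
#' @param graph a PangenomeGraph.
#' @param includeSelfLoops keep flagged self-loop edges.
#' @return an \code{igraph} graph with \code{weight} edge attribute.
#' @export
asIgraph <- function(graph, includeSelfLoops = FALSE) {
  e <- graph@edges
  if (!includeSelfLoops) e <- e[!e$self_loop, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[c("from", "to", "weight")], directed = FALSE,
    vertices = graph@nodes$family_id)
}
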