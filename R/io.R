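PARTITION_COLORS <- list(
  persistent = c(r = 237L, g = 118L, b = 0L),   # orange
  shell      = c(r = 46L,  g = 174L, b = 82L),  # green
  cloud      = c(r = 52L,  g = 120L, b = 219L)  # blue
)

encodeGenomeCounts <- function(egc, row) {
  v <- egc[row, ]
  nz <- which(v > 0)
  paste(paste0(colnames(egc)[nz], ":", v[nz]), collapse = ";")
}

#' Write a (partitioned) pangenome graph to GEXF or JSON
#'
#' GEXF 1.2 with node attributes (partition, gene count; partition colors
#' follow the orange/green/blue convention for persistent/shell/cloud as
#' viz attributes) and edge attributes (weight, per-genome adjacency
#' counts). The JSON format mirrors the same schema. Both round-trip
#' through \code{\link{readGraph}}.
#'
#' @param graph a \linkS4class{PangenomeGraph}.
#' @param path output file.
#' @param partitioning optional \linkS4class{Partitioning}.
#' @param format "gexf" or "json".
#' @return the path, invisibly.
#' @export
writeGraph <- function(graph, path, partitioning = NULL,
                       format = c("gexf", "json")) {
  format <- match.arg(format)
  nodes <- graph@nodes
  part <- if (!is.null(partitioning))
    unname(partitionLabels(partitioning)[nodes$family_id])
  else rep(NA_character_, nrow(nodes))
  edges <- graph@edges
  genomes_str <- vapply(seq_len(nrow(edges)),
                        function(r) encodeGenomeCounts(
                          graph@edgeGenomeCounts, r), character(1))

  if (format == "json") {
    obj <- list(
      n_genomes = graph@nGenomes,
      genomes = colnames(graph@edgeGenomeCounts),
      nodes = data.frame(id = nodes$family_id,
                         gene_count = nodes$gene_count,
                         partition = part),
      edges = data.frame(source = edges$from, target = edges$to,
                         weight = edges$weight, count = edges$count,
                         genomes = genomes_str))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(path))
  }

  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft",
    "xmlns:viz" = "http://www.gexf.net/1.2draft/viz", version = "1.2")
  g <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                           mode = "static",
                           ngenomes = as.character(graph@nGenomes))
  na <- xml2::xml_add_child(g, "attributes", class = "node")
  xml2::xml_add_child(na, "attribute", id = "0", title = "partition",
                      type = "string")
  xml2::xml_add_child(na, "attribute", id = "1", title = "gene_count",
                      type = "integer")
  ea <- xml2::xml_add_child(g, "attributes", class = "edge")
  xml2::xml_add_child(ea, "attribute", id = "0", title = "genomes",
                      type = "string")

  ns <- xml2::xml_add_child(g, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(ns, "node", id = nodes$family_id[i],
                              label = nodes$family_id[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    if (!is.na(part[i]))
      xml2::xml_add_child(av, "attvalue", `for` = "0", value = part[i])
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = as.character(nodes$gene_count[i]))
    if (!is.na(part[i]) && part[i] %in% names(PARTITION_COLORS)) {
      col <- PARTITION_COLORS[[part[i]]]
      xml2::xml_add_child(nd, "viz:color", r = as.character(col["r"]),
                          g = as.character(col["g"]),
                          b = as.character(col["b"]))
    }
  }
  es <- xml2::xml_add_child(g, "edges")
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(es, "edge", id = as.character(i - 1),
                              source = edges$from[i],
                              target = edges$to[i],
                              weight = format(edges$weight[i], digits = 15))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = genomes_str[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

decodeGenomeCounts <- function(strs, genomes) {
  egc <- Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(),
    dims = c(length(strs), length(genomes)),
    dimnames = list(NULL, genomes))
  for (r in seq_along(strs)) {
    if (!nzchar(strs[r])) next
    kv <- strsplit(strsplit(strs[r], ";", fixed = TRUE)[[1]], ":",
                   fixed = TRUE)
    for (p in kv) egc[r, p[1]] <- as.numeric(p[2])
  }
  methods::as(egc, "CsparseMatrix")
}

#' Read a pangenome graph from GEXF or JSON
#'
#' Inverse of \code{\link{writeGraph}}; recovers nodes, edges, weights and
#' per-genome adjacency counts. A stored partition node attribute is
#' returned alongside.
#'
#' @param path file written by \code{\link{writeGraph}}.
#' @param format "gexf" or "json" (guessed from the extension by default).
#' @return list with \code{graph} (\linkS4class{PangenomeGraph}) and
#'   \code{partition} (named character vector or NULL).
#' @export
readGraph <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else "gexf"
  if (!format %in% c("gexf", "json")) stop("unknown graph format: ", format)

  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- data.frame(family_id = obj$nodes$id,
                        gene_count = obj$nodes$gene_count)
    part <- if (!all(is.na(obj$nodes$partition)))
      stats::setNames(obj$nodes$partition, obj$nodes$id) else NULL
    egc <- decodeGenomeCounts(
      if (length(obj$edges)) obj$edges$genomes else character(),
      obj$genomes)
    count <- as.numeric(Matrix::rowSums(egc))
    edges <- data.frame(
      from = if (length(obj$edges)) obj$edges$source else character(),
      to = if (length(obj$edges)) obj$edges$target else character(),
      count = count, weight = count / obj$n_genomes,
      self_loop = if (length(obj$edges))
        obj$edges$source == obj$edges$target else logical())
    graph <- new("PangenomeGraph", nodes = nodes, edges = edges,
                 edgeGenomeCounts = egc,
                 nGenomes = as.integer(obj$n_genomes))
    return(list(graph = graph, partition = part))
  }

  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  gnode <- xml2::xml_find_first(doc, ".//graph")
  nG <- as.integer(xml2::xml_attr(gnode, "ngenomes"))
  nodeEls <- xml2::xml_find_all(doc, ".//nodes/node")
  ids <- xml2::xml_attr(nodeEls, "id")
  getAttv <- function(el, forId) {
    v <- xml2::xml_find_first(
      el, sprintf(".//attvalue[@for='%s']", forId))
    if (inherits(v, "xml_missing")) NA_character_
    else xml2::xml_attr(v, "value")
  }
  partv <- vapply(nodeEls, getAttv, character(1), forId = "0")
  genec <- as.integer(vapply(nodeEls, getAttv, character(1), forId = "1"))
  nodes <- data.frame(family_id = ids, gene_count = genec)
  part <- if (!all(is.na(partv))) stats::setNames(partv, ids) else NULL

  edgeEls <- xml2::xml_find_all(doc, ".//edges/edge")
  from <- xml2::xml_attr(edgeEls, "source")
  to <- xml2::xml_attr(edgeEls, "target")
  gstr <- vapply(edgeEls, getAttv, character(1), forId = "0")
  allGenomes <- sort(unique(unlist(lapply(gstr, function(s)
    vapply(strsplit(s, ";", fixed = TRUE)[[1]],
           function(p) strsplit(p, ":", fixed = TRUE)[[1]][1],
           character(1))))))
  egc <- decodeGenomeCounts(gstr, allGenomes)
  count <- as.numeric(Matrix::rowSums(egc))
  edges <- data.frame(from = from, to = to, count = count,
                      weight = count / nG, self_loop = from == to)
  graph <- new("PangenomeGraph", nodes = nodes, edges = edges,
               edgeGenomeCounts = egc, nGenomes = nG)
  list(graph = graph, partition = part)
}

#' Write the P/A matrix as Rtab or CSV
#'
#' Rtab: tab-separated families x genomes 0/1 table headed by genome ids
#' (first column "Gene"). CSV adds a partition column after the family id.
#' Families keep their matrix order.
#'
#' @param X a \linkS4class{PAMatrix}.
#' @param path output file.
#' @param partitioning optional \linkS4class{Partitioning} (CSV only).
#' @param format "rtab" or "csv".
#' @return the path, invisibly.
#' @export
writeMatrix <- function(X, path, partitioning = NULL,
                        format = c("rtab", "csv")) {
  format <- match.arg(format)
  M <- as.matrix(X@presence)
  storage.mode(M) <- "integer"
  if (format == "rtab") {
    df <- data.frame(Gene = rownames(M), M, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    part <- if (!is.null(partitioning))
      unname(partitionSubLabels(partitioning)[rownames(M)])
    else rep(NA_character_, nrow(M))
    df <- data.frame(family = rownames(M), partition = part, M,
                     check.names = FALSE)
    utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Fine partition labels (persistent / shell_k / cloud)
#' @param x a Partitioning.
#' @return named character vector of sub-labels.
#' @export
partitionSubLabels <- function(x) {
  stats::setNames(x@sublabel, x@familyIds)
}

#' Read a binary Rtab presence/absence table
#'
#' @param path Rtab file (first column family ids, then 0/1 genome
#'   columns).
#' @return a \linkS4class{PAMatrix}.
#' @export
readRtab <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- as.character(tab[[1]])
  if (!all(M %in% c(0, 1))) stop("Rtab values must be 0/1")
  PAMatrix(M)
}

#' Write / read a gene table as TSV
#'
#' The minimal genome/contig/gene-order record format the builders accept,
#' mirroring the gene-table columns.
#'
#' @param genes a gene table.
#' @param path TSV path.
#' @return \code{writeGeneTable}: the path invisibly;
#'   \code{readGeneTable}: a validated gene table.
#' @export
writeGeneTable <- function(genes, path) {
  utils::write.table(validateGeneTable(genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneTable
#' @export
readGeneTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c(start = "integer",
                                          end = "integer",
                                          circular = "logical"),
                           quote = "", stringsAsFactors = FALSE)
  validateGeneTable(tab)
}

#' Read a square genomic distance matrix (TSV)
#'
#' Header row and first column carry genome ids; values are symmetric
#' distances with zero diagonal (e.g. Mash distances).
#'
#' @param path TSV path.
#' @return numeric matrix with genome dimnames.
#' @export
readDistanceMatrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- as.character(tab[[1]])
  M
}

#' Write a synthetic truth table
#'
#' @param labels named true labels per family.
#' @param component named true component index per family.
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
writeTruth <- function(labels, component, path) {
  df <- data.frame(family_id = names(labels), true_label = unname(labels),
                   component = unname(component[names(labels)]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
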