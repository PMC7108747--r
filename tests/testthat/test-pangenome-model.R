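test_that("gene tables are validated and ordered by contig position", {
  g <- makeGenes(list(G1 = list(c1 = c("B", "A", "C"))))
  g$start <- c(200, 10, 900)
  g$end <- g$start + 100
  out <- validateGeneTable(g)
  expect_equal(out$family_id, c("A", "B", "C"))
  expect_error(validateGeneTable(g[0, ]), "empty")
  g2 <- g
  g2$gene_id[2] <- g2$gene_id[1]
  expect_error(validateGeneTable(g2), "duplicate gene_id")
  g3 <- g
  g3$end[1] <- g3$start[1] - 1
  expect_error(validateGeneTable(g3), "end")
})

test_that("GFF3 annotations are read with family mapping and ordered", {
  gff <- file.path(tempdir(), "G1.gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg1\tsrc\tCDS\t10\t100\t.\t+\t0\tID=g1",
    "ctg1\tsrc\tCDS\t900\t980\t.\t-\t0\tID=g3",
    "ctg1\tsrc\tCDS\t200\t300\t.\t+\t0\tID=g2",
    "ctg2\tsrc\tCDS\t5\t50\t.\t+\t0\tID=g4"), gff)
  fmap <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     family_id = c("A", "B", "C", "A"))
  genes <- readGff3(c(G1 = gff), fmap)
  expect_equal(genes$gene_id[genes$contig_id == "ctg1"],
               c("g1", "g2", "g3"))
  expect_equal(genes$start, c(10, 200, 900, 5))
  # missing family mapping names the offending gene
  expect_error(readGff3(c(G1 = gff), fmap[-3, ]), "g3")
})

test_that("P/A matrix marks presence of at least one family member", {
  g <- makeGenes(list(
    G1 = list(c1 = c("A", "B", "A", "A")),  # paralogs of A
    G2 = list(c1 = c("A"))))
  X <- buildPAMatrix(g)
  expect_equal(dim(X), c(2L, 2L))
  expect_equal(as.matrix(X)["A", ], c(G1 = 1, G2 = 1))
  expect_equal(as.matrix(X)["B", ], c(G1 = 1, G2 = 0))
  expect_error(buildPAMatrix(g[0, ]), "empty")
})

test_that("graph edges count adjacencies and weight by 1/N", {
  # (A,B) adjacent once in each of 2 genomes out of N=4
  g <- makeGenes(list(G1 = list(c1 = c("A", "B")),
                      G2 = list(c1 = c("A", "B")),
                      G3 = list(c1 = c("C")), G4 = list(c1 = c("D"))))
  gr <- buildPangenomeGraph(g)
  e <- edgeTable(gr)
  expect_equal(nrow(e), 1L)
  expect_equal(e$count, 2)
  expect_equal(e$weight, 0.5)
  expect_equal(gr@nGenomes, 4L)
})

test_that("repeated paralogous adjacency gives weight above 1", {
  # A-B adjacent twice in the single genome: w = 2/1 = 2
  g <- makeGenes(list(G1 = list(c1 = c("A", "B", "A", "B"))))
  gr <- buildPangenomeGraph(g)
  e <- edgeTable(gr)
  ab <- e[e$from == "A" & e$to == "B", ]
  expect_equal(ab$count, 3)  # A-B, B-A, A-B junctions
  g2 <- makeGenes(list(G1 = list(c1 = c("A", "B", "C", "A", "B"))))
  gr2 <- buildPangenomeGraph(g2)
  ab2 <- edgeTable(gr2)[edgeTable(gr2)$from == "A" &
                          edgeTable(gr2)$to == "B", ]
  expect_equal(ab2$count, 2)
  expect_equal(ab2$weight, 2.0)
})

test_that("circular contigs add the wrap-around edge", {
  g <- makeGenes(list(G1 = list(c1 = c("A", "B", "C"))), circular = TRUE)
  gr <- buildPangenomeGraph(g)
  e <- edgeTable(gr)
  expect_setequal(paste(e$from, e$to), c("A B", "B C", "A C"))
  glin <- makeGenes(list(G1 = list(c1 = c("A", "B", "C"))))
  expect_equal(nrow(edgeTable(buildPangenomeGraph(glin))), 2L)
})

test_that("adjacent paralogs of one family give a flagged self-loop", {
  g <- makeGenes(list(G1 = list(c1 = c("A", "A", "B"))))
  gr <- buildPangenomeGraph(g)
  e <- edgeTable(gr)
  expect_true(e$self_loop[e$from == "A" & e$to == "A"])
  expect_false(any(mrfEdges(gr, 10)$self_loop))
})

test_that("adjacency totals are conserved against a direct census", {
  for (s in 1:5) {
    set.seed(100 + s)
    sim <- simulatePangenome(F = 120, N = 12, seed = 100 + s)
    genes <- degradeGenomes(sim$genes, fragmentationRate = 0.1,
                            lossRate = 0.05, seed = s)
    gr <- buildPangenomeGraph(genes)
    expect_equal(sum(edgeTable(gr)$count), censusAdjacencies(genes))
  }
})

test_that("matrix and graph are consistent and deterministic", {
  sim <- simulatePangenome(F = 80, N = 10, seed = 11)
  X <- sim$pa
  gr <- buildPangenomeGraph(sim$genes)
  # every genome contributing to an edge carries both endpoint families
  M <- as.matrix(X)
  egc <- gr@edgeGenomeCounts
  for (r in seq_len(nrow(edgeTable(gr)))) {
    gens <- colnames(egc)[egc[r, ] > 0]
    expect_true(all(M[edgeTable(gr)$from[r], gens] == 1))
    expect_true(all(M[edgeTable(gr)$to[r], gens] == 1))
  }
  gr2 <- buildPangenomeGraph(sim$genes)
  expect_identical(edgeTable(gr), edgeTable(gr2))
  expect_identical(as.matrix(buildPAMatrix(sim$genes)),
                   as.matrix(buildPAMatrix(sim$genes)))
})

test_that("MRF edge set excludes hubs and honors the degree cap", {
  # star hub of degree 11 plus a 5-node path
  hub <- lapply(sprintf("L%02d", 1:11), function(l) c("HUB", l))
  names(hub) <- sprintf("c%02d", 1:11)
  g <- makeGenes(list(G1 = hub, G2 = list(p = c("P1", "P2", "P3", "P4",
                                                "P5"))))
  gr <- buildPangenomeGraph(g)
  expect_equal(unname(nodeDegrees(gr)["HUB"]), 11L)
  me <- mrfEdges(gr, 10)
  expect_false(any(me$from == "HUB" | me$to == "HUB"))
  expect_equal(nrow(me), 4L)  # the path edges survive
  expect_equal(nrow(mrfEdges(gr, 0)), 0L)
  expect_error(mrfEdges(gr, -1), "maxDegree")
  # hub nodes remain in the node set (still partitionable)
  expect_true("HUB" %in% familyNames(gr))
})

test_that("genome subsetting recomputes weights with the subset N", {
  g <- makeGenes(list(G1 = list(c1 = c("A", "B")),
                      G2 = list(c1 = c("A", "B")),
                      G3 = list(c1 = c("A", "C"))))
  gr <- buildPangenomeGraph(g)
  sub <- subsetGraphGenomes(gr, c("G1", "G2"))
  e <- edgeTable(sub)
  expect_equal(nrow(e), 1L)  # A-C edge dropped with G3
  expect_equal(e$weight, 1.0)  # 2 adjacencies / N = 2
})
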