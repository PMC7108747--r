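test_that("truth parameters encode the documented fixed conditions", {
  p3 <- truthParams(10)
  expect_equal(p3@pi, c(0.3, 0.2, 0.5))
  expect_equal(p3@epsilon[, 1], c(0.05, 0.3, 0.05))
  expect_equal(p3@mu[1, ], rep(1, 10))
  expect_equal(p3@mu[2, ], c(rep(1, 5), rep(0, 5)))
  expect_equal(p3@mu[3, ], rep(0, 10))
  p4 <- truthParams(10, patterns = 4)
  expect_equal(p4@pi, c(0.3, 0.15, 0.15, 0.4))
  expect_equal(p4@mu[2, ] + p4@mu[3, ], rep(1, 10))  # antagonistic blocks
  expect_error(truthParams(10, patterns = 5), "3 or 4")
})

test_that("generated P/A has a U-shaped frequency spectrum", {
  gp <- generatePA(2000, 50, seed = 81)
  occ <- Matrix::rowSums(gp$pa@presence)
  expect_true(all(occ >= 1))  # row-sum invariant
  lo <- mean(occ <= 5); mid <- mean(occ > 15 & occ <= 35)
  hi <- mean(occ >= 45)
  expect_gt(lo, mid); expect_gt(hi, mid)  # U shape
  # marginal presence calibrated against the mixture within 3 SE
  p <- truthParams(50)
  perFam <- sum(p@pi * rowMeans(p@mu * (1 - p@epsilon) +
                                  (1 - p@mu) * p@epsilon))
  expected <- perFam * 50
  se <- sqrt(expected)  # crude Poisson-scale bound per family row mean
  expect_lt(abs(mean(occ) - expected), 3 * se / sqrt(2000) * 50)
  expect_equal(unname(gp$labels[gp$component == 1][1]), "persistent")
})

test_that("genome layout is circular with island-coherent neighborhoods", {
  sim <- simulatePangenome(F = 300, N = 20, seed = 82)
  expect_true(all(sim$genes$circular))
  expect_equal(unique(sim$genes$contig_id), "contig_1")
  gr <- buildPangenomeGraph(sim$genes)
  e <- edgeTable(gr)
  lab <- sim$labels
  same <- mean(lab[e$from] == lab[e$to])
  # label assortativity: observed same-label edge fraction beats 20
  # random permutations of labels over families
  set.seed(1)
  perm <- replicate(20, {
    pl <- stats::setNames(sample(lab), names(lab))
    mean(pl[e$from] == pl[e$to])
  })
  expect_gt(same, max(perm))
})

test_that("degradation with zero rates is the identity", {
  sim <- simulatePangenome(F = 100, N = 10, seed = 83)
  out <- degradeGenomes(sim$genes, 0, 0)
  expect_equal(out, validateGeneTable(sim$genes))
  # full fragmentation -> every contig holds a single gene
  frag <- degradeGenomes(sim$genes, 1, 0, seed = 1)
  expect_false(any(frag$circular))
  expect_equal(max(table(paste(frag$genome_id, frag$contig_id))), 1L)
  expect_equal(nrow(frag), nrow(sim$genes))
  # loss shrinks the table roughly by the loss rate
  lost <- degradeGenomes(sim$genes, 0, 0.3, seed = 2)
  expect_lt(nrow(lost), nrow(sim$genes))
  expect_gt(nrow(lost), 0.5 * nrow(sim$genes))
  expect_error(degradeGenomes(sim$genes, -0.1, 0), "rates")
})

test_that("simulation is seed-reproducible and exposes its truth", {
  a <- simulatePangenome(F = 120, N = 12, seed = 84)
  b <- simulatePangenome(F = 120, N = 12, seed = 84)
  expect_identical(as.matrix(a$pa), as.matrix(b$pa))
  expect_identical(a$genes, b$genes)
  expect_identical(a$labels, b$labels)
  c2 <- simulatePangenome(F = 120, N = 12, seed = 85)
  expect_false(identical(as.matrix(a$pa), as.matrix(c2$pa)))
  expect_setequal(unique(a$labels), c("persistent", "shell", "cloud"))
  expect_true(all(lengths(a$islands) <= 8))
  expect_setequal(unlist(a$islands), names(a$component)[a$component != 1])
})

test_that("graph smoothing protects islands against moderate gene loss", {
  # after loss, persistent recall of NEM should stay at least as high as
  # the soft-core heuristic's recall of the same truth
  hitsNem <- hitsSoft <- numeric(5)
  for (s in 1:5) {
    sim <- simulatePangenome(F = 300, N = 30, seed = 860 + s)
    genes <- degradeGenomes(sim$genes, lossRate = 0.05, seed = s)
    X <- buildPAMatrix(genes)
    g <- buildPangenomeGraph(genes)
    fit <- runNEM(X, g, 3)
    lab <- partitionLabels(fit$partitioning)
    truthP <- names(sim$labels)[sim$labels == "persistent"]
    truthP <- intersect(truthP, familyNames(X))
    hitsNem[s] <- mean(lab[truthP] == "persistent")
    occ <- Matrix::rowSums(X@presence)
    soft <- names(occ)[occ >= ceiling(0.95 * ncol(X))]
    hitsSoft[s] <- mean(truthP %in% soft)
  }
  expect_gte(mean(hitsNem), mean(hitsSoft))
  expect_gt(mean(hitsNem), 0.9)
})

test_that("label accuracy scores only the shared family universe", {
  part <- new("Partitioning", familyIds = c("a", "b", "c"),
              labels = c("persistent", "shell", "cloud"),
              sublabel = c("persistent", "shell", "cloud"),
              component = 1:3, K = 3L)
  truth <- c(a = "persistent", b = "cloud", c = "cloud", d = "shell")
  expect_equal(labelAccuracy(part, truth), 2 / 3)
})
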