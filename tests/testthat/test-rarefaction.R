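test_that("allowed absences form a stair-step with the expected period", {
  a <- allowedAbsences(1:100, 0.95)
  # floor(0.05 n): increments exactly at multiples of 20
  expect_equal(a, floor(0.05 * (1:100) + 1e-9))
  expect_equal(which(diff(a) == 1), c(19, 39, 59, 79, 99))
  # equivalent: soft-core count n - ceiling(0.95 n) has period 1/(1-t)
  expect_equal((1:100) - ceiling(0.95 * (1:100) - 1e-9), a)
  a90 <- allowedAbsences(1:30, 0.9)
  expect_equal(which(diff(a90) == 1), seq(9, 29, by = 10))
})

test_that("component counts honor exact/soft core definitions", {
  M <- rbind(core = rep(1, 20),
             soft = c(rep(1, 19), 0),      # 1 absence allowed at n = 20
             half = c(rep(1, 10), rep(0, 10)),
             rare = c(1, rep(0, 19)))
  colnames(M) <- paste0("g", 1:20)
  X <- PAMatrix(M)
  cc <- componentCounts(X)
  expect_equal(unname(cc["pangenome"]), 4)
  expect_equal(unname(cc["exact_core"]), 1)
  expect_equal(unname(cc["soft_core"]), 2)
  expect_equal(unname(cc["soft_accessory"]), 2)
  expect_equal(unname(cc["exact_accessory"]), 3)
  expect_true(is.na(cc["persistent"]))
  part <- new("Partitioning", familyIds = rownames(M),
              labels = c("persistent", "persistent", "shell", "cloud"),
              sublabel = c("persistent", "persistent", "shell", "cloud"),
              component = c(1L, 1L, 2L, 3L), K = 3L)
  cc2 <- componentCounts(X, part)
  expect_equal(unname(cc2[c("persistent", "shell", "cloud")]), c(2, 1, 1))
})

test_that("rarefaction curves are monotone-in-median and reproducible", {
  sim <- simulatePangenome(F = 200, N = 25, seed = 61)
  rc <- rarefactionCurves(sim$pa, maxN = 25, reps = 8, seed = 1,
                          partitionMode = "none")
  expect_s4_class(rc, "RarefactionResult")
  expect_equal(nrow(rc@samples), 8 * length(RAREFACTION_COMPONENTS) * 25)
  qp <- rc@quartiles[rc@quartiles$component == "pangenome", ]
  expect_true(all(diff(qp$median) >= 0))        # pangenome accumulates
  qc <- rc@quartiles[rc@quartiles$component == "exact_core", ]
  # exact core shrinks in tendency (medians of finite reps can wiggle)
  expect_gt(qc$median[1], qc$median[nrow(qc)])
  expect_lt(stats::cor(qc$n, qc$median, method = "spearman"), -0.8)
  rc2 <- rarefactionCurves(sim$pa, maxN = 25, reps = 8, seed = 1,
                           partitionMode = "none")
  expect_identical(rc@samples, rc2@samples)
  expect_error(rarefactionCurves(sim$pa, reps = 0,
                                 partitionMode = "none"), "reps")
  expect_error(rarefactionCurves(sim$pa, maxN = 25, reps = 2), "KFull")
})

test_that("partitioned rarefaction fills persistent/shell/cloud counts", {
  sim <- simulatePangenome(F = 150, N = 20, seed = 62)
  g <- buildPangenomeGraph(sim$genes)
  rc <- rarefactionCurves(sim$pa, graph = g, maxN = 20, reps = 3,
                          seed = 2, partitionMode = "fixed", KFull = 3)
  big <- rc@samples[rc@samples$n == 20, ]
  byComp <- tapply(big$count, big$component, mean)
  expect_false(anyNA(byComp[c("persistent", "shell", "cloud")]))
  expect_equal(unname(byComp["persistent"] + byComp["shell"] +
                        byComp["cloud"]),
               unname(byComp["pangenome"]))
})

test_that("Heaps' law fit recovers exact and noisy power laws", {
  n <- rep(16:60, each = 5)
  exact <- data.frame(n = n, count = 100 * n^0.5)
  fit <- fitHeaps(exact)
  expect_equal(fit$kappa, 100, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-6)
  expect_true(fit$converged)
  set.seed(77)
  noisy <- data.frame(n = n, count = 100 * n^0.5 * exp(rnorm(length(n),
                                                             0, 0.02)))
  fn <- fitHeaps(noisy)
  expect_lt(abs(fn$gamma - 0.5), 0.05)
  # closed component: constant counts -> gamma ~ 0
  flat <- data.frame(n = n, count = rep(42, length(n)))
  ff <- fitHeaps(flat)
  expect_equal(ff$gamma, 0, tolerance = 1e-8)
  expect_equal(ff$kappa, 42, tolerance = 1e-6)
  # small subsets are excluded from the fit
  spiked <- rbind(data.frame(n = rep(2:15, each = 2), count = 1e6), exact)
  fs <- fitHeaps(spiked)
  expect_equal(fs$gamma, 0.5, tolerance = 1e-6)
  expect_error(fitHeaps(data.frame(n = c(16, 17), count = c(1, 2))),
               "3 distinct")
})

test_that("IQR area matches hand-computed trapezoids", {
  q <- data.frame(n = c(1, 2, 4), q1 = c(0, 1, 1), q3 = c(2, 3, 5))
  # widths 2, 2, 4 -> (2+2)/2*1 + (2+4)/2*2 = 2 + 6
  expect_equal(iqrArea(q), 8)
  expect_equal(iqrArea(q[c(3, 1, 2), ]), 8)  # order-insensitive
  qz <- data.frame(n = 1:5, q1 = 3, q3 = 3)
  expect_equal(iqrArea(qz), 0)
  expect_error(iqrArea(q[1, ]), "2 sizes")
})
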