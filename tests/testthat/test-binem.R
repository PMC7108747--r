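test_that("triangular initialization follows the rescaled formulas", {
  p3 <- triangularInit(3, 4)
  expect_equal(p3@pi, rep(1 / 3, 3))
  expect_equal(p3@mu, rbind(rep(1, 4), rep(0, 4), rep(0, 4)))
  expect_equal(p3@epsilon[, 1], c(0.25, 0.50, 0.25))
  p4 <- triangularInit(4, 2)
  expect_equal(p4@mu[, 1], c(1, 1, 0, 0))
  # central tie broken deterministically so no two components share
  # (mu, epsilon); see the methods vignette
  expect_equal(p4@epsilon[, 1], c(0.25, 0.5, 0.375, 0.25))
  # every K up to 20: epsilon within (0, 1/2], component densities distinct
  for (K in 2:20) {
    p <- triangularInit(K, 3)
    expect_true(all(p@epsilon > 0 & p@epsilon <= 0.5))
    dens <- apply(cbind(p@mu[, 1], p@epsilon[, 1]), 1, function(r)
      if (r[2] >= 0.5) "uniform" else paste(r, collapse = "/"))
    expect_false(anyDuplicated(dens) > 0)
  }
  expect_error(triangularInit(1, 5), "K")
})

test_that("family log-density matches the printed Bernoulli factors", {
  p <- new("BMMParams", K = 2L, pi = c(0.5, 0.5),
           mu = rbind(1, 0), epsilon = rbind(0.25, 0.25),
           constrained = TRUE)
  expect_equal(familyLogDensity(1, 1, p), log(0.75))
  expect_equal(familyLogDensity(0, 1, p), log(0.25))
  p2 <- new("BMMParams", K = 1L, pi = 1,
            mu = matrix(c(1, 0), 1), epsilon = matrix(c(0.1, 0.2), 1),
            constrained = FALSE)
  expect_equal(familyLogDensity(c(1, 0), 1, p2), log(0.9 * 0.8))
})

test_that("E-step posteriors match a brute-force mixture oracle", {
  set.seed(42)
  for (rep in 1:8) {
    F <- sample(2:8, 1); N <- sample(1:4, 1); K <- sample(2:3, 1)
    X <- randomPA(F, N)
    params <- randomParams(K, N)
    es <- eStep(X, params)
    bf <- bruteForceMixture(X, params)
    expect_equal(unname(es$posterior), unname(bf$posterior),
                 tolerance = 1e-12)
    expect_equal(es$loglik, bf$loglik, tolerance = 1e-12)
    expect_equal(rowSums(es$posterior), rep(1, F), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate mixtures give symmetric or concentrated posteriors", {
  X <- randomPA(5, 3)
  same <- new("BMMParams", K = 2L, pi = c(0.5, 0.5),
              mu = rbind(rep(1, 3), rep(1, 3)),
              epsilon = matrix(0.2, 2, 3), constrained = TRUE)
  expect_equal(unname(eStep(X, same)$posterior),
               matrix(0.5, 5, 2))
  conc <- new("BMMParams", K = 2L, pi = c(1 - 1e-300, 1e-300),
              mu = rbind(rep(1, 3), rep(0, 3)),
              epsilon = matrix(0.2, 2, 3), constrained = TRUE)
  expect_true(all(eStep(X, conc)$posterior[, 1] > 0.999))
})

test_that("M-step recovers weighted means, ties and constrained pooling", {
  # hard responsibilities, one active component, column [1,1,0]
  X <- matrix(c(1, 1, 0), 3, 1, dimnames = list(c("a", "b", "c"), "g1"))
  T <- cbind(rep(1, 3), rep(0, 3))
  expect_warning(p <- mStep(X, T), "empty")
  expect_equal(unname(p@mu[1, 1]), 1)
  expect_equal(unname(p@epsilon[1, 1]), 1 / 3)
  # uniform responsibilities -> identical components
  Tu <- matrix(0.5, 3, 2)
  pu <- mStep(X, Tu)
  expect_equal(pu@mu[1, ], pu@mu[2, ])
  expect_equal(pu@epsilon[1, ], pu@epsilon[2, ])
  # constrained pooling averages per-genome mismatch rates
  X2 <- rbind(c(1, 1), c(1, 1), c(1, 1), c(1, 1), c(1, 1),
              c(0, 1), c(1, 0), c(1, 0), c(1, 0), c(0, 0))
  X2 <- X2[c(1:5, 6, 7:9, 10), ]
  rownames(X2) <- paste0("f", 1:10)
  T2 <- matrix(1, 10, 1)
  # mu = (1,1); mismatch rates: col1 3/10, col2 5/10 -> pooled 0.4
  X2[10, ] <- c(0, 0)
  p2 <- mStep(X2, T2, constrained = TRUE)
  mm <- colMeans(abs(sweep(X2, 2, p2@mu[1, ])))
  expect_equal(unname(p2@epsilon[1, ]), rep(mean(mm), 2))
  p2f <- mStep(X2, T2, constrained = FALSE)
  expect_equal(unname(p2f@epsilon[1, ]), unname(mm))
  # exact 0.5 weighted presence -> mu = 0
  X3 <- matrix(c(1, 0), 2, 1, dimnames = list(c("a", "b"), "g"))
  expect_equal(unname(mStep(X3, matrix(1, 2, 1))@mu[1, 1]), 0)
})

test_that("EM log-likelihood is non-decreasing and converges", {
  set.seed(7)
  gp <- generatePA(150, 12, seed = 7)
  fit <- runBinEM(gp$pa, 3)
  expect_true(all(diff(fit$loglik) > -1e-9))
  expect_error(runBinEM(gp$pa, 200), "exceed")
  # a hard-clustered fixed point converges immediately
  Xh <- rbind(matrix(1, 10, 6), matrix(0, 10, 6))
  rownames(Xh) <- paste0("f", 1:20)
  colnames(Xh) <- paste0("g", 1:6)
  fith <- runBinEM(Xh, 2)
  expect_lte(length(fith$loglik), 5)
  ll <- fith$loglik
  expect_lt(abs(ll[length(ll)] - ll[length(ll) - 1]), 1e-6 * abs(ll[1]))
})

test_that("components end sorted by presence and recover true parameters", {
  tp <- truthParams(50)
  ok_order <- TRUE
  for (s in 1:20) {
    gp <- generatePA(1000, 50, seed = 2000 + s)
    fit <- runBinEM(gp$pa, 3)
    p <- fit$params@mu * (1 - fit$params@epsilon) +
      (1 - fit$params@mu) * fit$params@epsilon
    ok_order <- ok_order && !is.unsorted(rev(rowMeans(p)))
    expect_lt(max(abs(fit$params@pi - tp@pi)), 0.05)
    expect_lt(max(abs(rowMeans(fit$params@epsilon) - rowMeans(tp@epsilon))),
              0.05)
    expect_gte(labelAccuracy(assignPartitions(fit$posterior), gp$labels),
               0.95)
  }
  expect_true(ok_order)
})

test_that("partition assignment uses a strict 0.5 posterior rule", {
  post <- rbind(c(0.9, 0.05, 0.05),
                c(0.45, 0.35, 0.20),
                c(0.5, 0.5, 0.0),
                c(0.1, 0.2, 0.7))
  rownames(post) <- paste0("f", 1:4)
  part <- assignPartitions(post)
  expect_equal(unname(partitionLabels(part)),
               c("persistent", "shell", "shell", "cloud"))
  # undecided families record their best shell component
  expect_equal(part@component[2], 2L)
  # K = 4: shell sub-labels expose the component
  post4 <- rbind(c(0.1, 0.8, 0.05, 0.05), c(0.05, 0.05, 0.8, 0.1))
  rownames(post4) <- c("a", "b")
  p4 <- assignPartitions(post4)
  expect_equal(unname(partitionSubLabels(p4)), c("shell_2", "shell_3"))
  expect_equal(unname(partitionLabels(p4)), c("shell", "shell"))
})
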