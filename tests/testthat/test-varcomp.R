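mkZ <- function(h) {
  haps <- sort(unique(h))
  Z <- outer(h, haps, "==") * 1
  colnames(Z) <- as.character(haps)
  Z
}

test_that("model 1 reproduces group-mean effects", {
  Z <- mkZ(c(1, 1, 2, 2))
  f <- fitModel1(c(1, 1, 3, 3), Z)
  expect_equal(f@mu, 2)
  expect_equal(unname(f@effects), c(-1, 1))
  expect_equal(f@sigma2E, 0)
  # constant y: all effects zero
  fc <- fitModel1(rep(5, 6), mkZ(c(1, 1, 2, 2, 3, 3)))
  expect_true(all(fc@effects == 0))
  # unbalanced case against the least-squares oracle
  y <- c(0, 2, 2, 4, 4, 4)
  h <- c(1, 1, 2, 2, 2, 2)
  fu <- fitModel1(y, mkZ(h))
  lmfit <- lm(y ~ factor(h))
  expect_equal(fitted(lmfit), fu@mu + as.vector(mkZ(h) %*% fu@effects),
               ignore_attr = TRUE)
  expect_equal(unname(fu@effects),
               as.vector(tapply(y, h, mean) - mean(y)))
  expect_error(fitModel1(c(1, 2), mkZ(c(1, 2))), "saturated")
})

test_that("model 2 recovers a null cis component", {
  pan <- simulateDiversePanel(makeFounders(12, 10), 400, 5, seed = 61)
  H <- relValues(buildHRM(buildDesignMatrix(pan, "r0001")))
  set.seed(62)
  est <- replicate(50, {
    y <- rnorm(400)
    fitModel2(y, H)@sigma2Cis / var(y)
  })
  expect_lte(median(est), 0.02)
})

test_that("model 2 tolerates a non-identifiable identity kernel", {
  set.seed(63)
  y <- rnorm(50, sd = 2)
  f <- fitModel2(y, diag(50))
  expect_s4_class(f, "VarCompFit")
  expect_lt(abs((f@sigma2Cis + f@sigma2E) / var(y) - 1), 0.2)
})

test_that("model 2 REML recovers simulated variances and matches the grid oracle", {
  pan <- simulateDiversePanel(makeFounders(20, 10), 400, 5, seed = 64)
  H <- relValues(buildHRM(buildDesignMatrix(pan, "r0001")))
  L <- t(chol(H + diag(400) * 1e-10))
  set.seed(65)
  est <- t(replicate(100, {
    y <- as.vector(L %*% rnorm(400)) + rnorm(400)
    f <- fitModel2(y, H)
    c(f@sigma2Cis, f@sigma2E)
  }))
  expect_lt(abs(median(est[, 1]) - 1), 0.15)
  expect_lt(abs(median(est[, 2]) - 1), 0.15)

  # grid-search oracle agreement on small instances
  set.seed(66)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    panS <- simulateDiversePanel(makeFounders(6, 8), n, 3, seed = 100 + i)
    Hs <- relValues(buildHRM(buildDesignMatrix(panS, "r0001")))
    Ls <- t(chol(Hs + diag(n) * 1e-10))
    y <- as.vector(Ls %*% rnorm(n)) * runif(1, 0.5, 2) + rnorm(n)
    f <- fitModel2(y, Hs)
    or <- gridRemlRatio(y, Hs)
    ratio <- if (f@sigma2E > 0) f@sigma2Cis / f@sigma2E else Inf
    step <- or$grid[2] / or$grid[1]
    if (or$which == 1) {
      expect_lte(ratio, or$grid[1] * step)
    } else if (or$which == length(or$grid)) {
      expect_gte(ratio, or$grid[length(or$grid)] / step)
    } else {
      expect_gte(ratio, or$ratio / step)
      expect_lte(ratio, or$ratio * step)
    }
  }
})

test_that("model 3 is consistent with model 2 when trans variance is null", {
  pan <- simulateDiversePanel(makeFounders(15, 40), 300, 5, seed = 71)
  Z <- buildDesignMatrix(pan, "r0001")
  H <- relValues(buildHRM(Z))
  Ht <- relValues(buildTransHRM(pan))
  L <- t(chol(H + diag(300) * 1e-10))
  set.seed(72)
  y <- as.vector(L %*% rnorm(300)) + rnorm(300)
  f2 <- fitModel2(y, H)
  f3 <- fitModel3(y, H, Ht)
  tot <- var(y)
  expect_lt(f3@sigma2Trans / tot, 0.1)
  expect_lt(abs(f3@sigma2Cis - f2@sigma2Cis) / tot, 0.05)
  expect_lt(abs(f3@sigma2E - f2@sigma2E) / tot, 0.05)
})

test_that("model 3 restricted likelihood at the optimum dominates the truth", {
  pan <- simulateDiversePanel(makeFounders(10, 15), 120, 4, seed = 73)
  Z <- buildDesignMatrix(pan, "r0001")
  Hc <- relValues(buildHRM(Z))
  Ht <- relValues(buildTransHRM(pan))
  set.seed(74)
  for (i in 1:5) {
    truth <- c(cis = runif(1, 0.2, 2), trans = runif(1, 0.2, 2),
               e = runif(1, 0.2, 2))
    V <- truth[1] * Hc + truth[2] * Ht + truth[3] * diag(120)
    y <- as.vector(t(chol(V)) %*% rnorm(120))
    f <- fitModel3(y, Hc, Ht)
    llTruth <- hare:::remlLoglik(y, list(Hc, Ht, diag(120)), truth)
    expect_gte(f@loglik + 1e-6, llTruth)
  }
})

test_that("low-rank and dense model-3 paths agree", {
  pan <- simulateDiversePanel(makeFounders(8, 12), 80, 4, seed = 75)
  se <- simulateExpression(pan, simScenario(nGenes = 3, seed = 76))
  Y <- SummarizedExperiment::assay(se, 1)
  Z <- buildDesignMatrix(pan, "r0001")
  Ht <- relValues(buildTransHRM(pan))
  fd <- fitModel3(Y[1, ], buildHRM(Z), Ht)
  fl <- fitModel3(Y[1, ], Z = Z, Htrans = Ht)
  expect_equal(varComponents(fd), varComponents(fl), tolerance = 1e-5)
  expect_equal(fd@loglik, fl@loglik, tolerance = 1e-6)
})

test_that("collinear kernels are flagged as unidentifiable", {
  pan <- tinyPanel(n = 40, seed = 77)
  H <- relValues(buildHRM(buildDesignMatrix(pan, "r0001")))
  set.seed(78)
  y <- rnorm(40)
  f <- fitModel3(y, H, H)
  expect_true("identifiability" %in% f@flags)
})

test_that("variance decomposition satisfies its algebraic identities", {
  mk <- function(sc, st, se) new("VarCompFit", model = 3L, mu = 0,
    sigma2Cis = sc, sigma2Trans = st, sigma2E = se, loglik = 0,
    converged = TRUE, nUsed = 10L, effects = numeric(), flags = character())
  d <- decomposeVariance(mk(1, 1, 2))
  expect_equal(unname(d), c(0.25, 0.25, 0.5, 0.5))
  d2 <- decomposeVariance(mk(0, 1, 1))
  expect_equal(unname(d2[c("h2_cis", "cis_share_of_heritable")]), c(0, 0))
  d3 <- decomposeVariance(mk(1, 2, 1))
  expect_equal(unname(d3[c("heritable_prop", "cis_share_of_heritable")]),
               c(0.75, 1 / 3))
  expect_equal(d3[["h2_cis"]] + d3[["h2_trans"]], d3[["heritable_prop"]],
               tolerance = 1e-12)
  expect_true(all(is.na(decomposeVariance(mk(0, 0, 0)))))
  expect_error(decomposeVariance(fitModel1(c(1, 2, 3, 4),
                                           mkZ(c(1, 1, 2, 2)))), "model-3")
})

test_that("estimated shares are invariant to rescaling the response", {
  pan <- tinyPanel(n = 60, nr = 15, seed = 79)
  se <- simulateExpression(pan, simScenario(nGenes = 4, seed = 80))
  y <- SummarizedExperiment::assay(se, 1)[1, ]
  Z <- buildDesignMatrix(pan, "r0001")
  Ht <- relValues(buildTransHRM(pan))
  f1 <- fitModel3(y, Z = Z, Htrans = Ht)
  f2 <- fitModel3(y * 7, Z = Z, Htrans = Ht)
  expect_equal(decomposeVariance(f1), decomposeVariance(f2),
               tolerance = 1e-4)
  expect_equal(f2@sigma2E / f1@sigma2E, 49, tolerance = 1e-3)
})

test_that("partitionExpression drops lines missing at the focal range", {
  pan <- tinyPanel(n = 50, nr = 10, seed = 81)
  se <- simulateExpression(pan, simScenario(nGenes = 5, seed = 82))
  calls <- haplotypeCalls(pan)
  calls[1:3, 1] <- NA
  panNA <- HaplotypePanel(calls, refRanges(pan))
  vc <- partitionExpression(se, panNA, model = 3)
  expect_equal(vc$n_used[1], 47L)
  expect_equal(vc$n_used[2], 50L)
  expect_true(all(vc$sigma2_cis >= 0 & vc$sigma2_e >= 0))
})
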