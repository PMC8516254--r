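randX <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(paste0("l", seq_len(n)),
                                             paste0("f", seq_len(p))))
}

test_that("closed-form ridge solves the stated objective", {
  # gradient-descent oracle on a random n < p instance
  X <- randX(20, 50, 111)
  set.seed(112)
  y <- rnorm(20)
  for (lambda in c(0.5, 5, 50)) {
    m <- fitRidge(X, y, lambda)
    Xs <- standardizeLike(X, m)
    bOracle <- gdRidge(Xs, y - mean(y), lambda)
    expect_lt(max(abs(m$beta * m$scale - bOracle)), 1e-6)
  }
  # primal normal-equations oracle on an n > p instance
  X2 <- randX(60, 15, 113)
  set.seed(114)
  y2 <- rnorm(60)
  m2 <- fitRidge(X2, y2, 2)
  Xs2 <- standardizeLike(X2, m2)
  bPrimal <- solve(crossprod(Xs2) + 2 * diag(15), crossprod(Xs2, y2 - mean(y2)))
  expect_lt(max(abs(m2$beta * m2$scale - as.vector(bPrimal))), 1e-8)
  # dual form agrees on the n < p instance
  m1 <- fitRidge(X, y, 5)
  Xs1 <- standardizeLike(X, m1)
  bDual <- crossprod(Xs1, solve(tcrossprod(Xs1) + 5 * diag(20),
                                y - mean(y)))
  expect_lt(max(abs(m1$beta * m1$scale - as.vector(bDual))), 1e-8)
})

test_that("extreme penalties shrink fully and zero-variance features drop", {
  X <- randX(30, 10, 115)
  set.seed(116)
  y <- rnorm(30)
  m <- fitRidge(X, y, 1e8 * sum(X^2))
  expect_lt(sqrt(sum(m$beta^2)), 1e-6)
  expect_error(fitRidge(X, y, -1), ">= 0")
  Xz <- cbind(X, const = 1)
  expect_warning(mz <- fitRidge(Xz, y, 1), "zero-variance")
  expect_false("const" %in% mz$kept)
})

test_that("ridge predictions are invariant to affine feature rescaling", {
  X <- randX(40, 8, 117)
  set.seed(118)
  y <- rnorm(40)
  m <- fitRidge(X, y, 3)
  X2 <- X
  X2[, 2] <- 10 * X2[, 2] - 7
  X2[, 5] <- -0.2 * X2[, 5] + 100
  m2 <- fitRidge(X2, y, 3)
  expect_lt(max(abs(predict(m, X) - predict(m2, X2))), 1e-8)
})

test_that("cross-validated lambda selection tracks the noise regime", {
  # pure-noise response: heavy shrinkage (top decile) most of the time
  top <- vapply(1:25, function(s) {
    X <- randX(60, 30, 200 + s)
    set.seed(300 + s)
    y <- rnorm(60)
    g <- sort(30 * 10^seq(-4, 4, length.out = 50))
    l <- selectLambdaCV(X, y, grid = g, kFolds = 5, seed = 400 + s)
    as.numeric(l) >= g[46]
  }, TRUE)
  expect_gte(mean(top), 0.7)
  # noise-free linear signal, p < n: light shrinkage (bottom decile)
  bottom <- vapply(1:25, function(s) {
    X <- randX(60, 10, 500 + s)
    set.seed(600 + s)
    y <- as.vector(X %*% rnorm(10))
    g <- sort(10 * 10^seq(-4, 4, length.out = 50))
    l <- selectLambdaCV(X, y, grid = g, kFolds = 5, seed = 700 + s)
    as.numeric(l) <= g[5]
  }, TRUE)
  expect_gte(mean(bottom), 0.8)
  # single-point grid returns that lambda; ties break to larger lambda
  X <- randX(20, 5, 801)
  set.seed(802)
  y <- rnorm(20)
  expect_equal(as.numeric(selectLambdaCV(X, y, grid = 7, kFolds = 4)), 7)
  expect_error(selectLambdaCV(X, y, grid = numeric(0)), "empty")
  expect_error(selectLambdaCV(X[1:5, ], y[1:5], kFolds = 10), "kFolds")
})

test_that("Pearson accuracy matches hand computations and signals degeneracy", {
  y <- c(1, 2, 3, 4)
  expect_equal(predictionAccuracy(y, y), 1)
  expect_equal(predictionAccuracy(y, -y), -1)
  expect_equal(predictionAccuracy(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(a <- predictionAccuracy(y, rep(1, 4)), "constant")
  expect_true(is.na(a))
  expect_error(predictionAccuracy(y, y[1:3]), "mismatch")
})

test_that("within-panel evaluation behaves at the signal extremes", {
  X <- randX(100, 10, 121)
  set.seed(122)
  beta <- rnorm(10)
  yLin <- as.vector(X %*% beta)
  names(yLin) <- rownames(X)
  res <- evaluateWithinPanel(X, yLin, nRepeats = 5, seed = 123, kFolds = 5,
                             grid = 10 * 10^seq(-4, 2, length.out = 20))
  expect_gte(meanAccuracy(res), 0.99)
  # default repeats: exactly 20 accuracies
  resD <- evaluateWithinPanel(X, yLin, seed = 124, kFolds = 5,
                              grid = 10 * 10^seq(-4, 2, length.out = 10))
  expect_length(accuracies(resD), 20L)
  # independent response: mean accuracy near zero
  Xn <- randX(250, 20, 125)
  set.seed(126)
  yNull <- rnorm(250)
  names(yNull) <- rownames(Xn)
  resN <- evaluateWithinPanel(Xn, yNull, nRepeats = 20, seed = 127,
                              kFolds = 5,
                              grid = 20 * 10^seq(-2, 4, length.out = 15))
  expect_lt(abs(meanAccuracy(resN)), 0.1)
})

test_that("within-panel splits are reproducible and reusable", {
  X <- randX(50, 8, 131)
  set.seed(132)
  y <- as.vector(X %*% rnorm(8)) + rnorm(50)
  names(y) <- rownames(X)
  g <- 8 * 10^seq(-3, 3, length.out = 10)
  r1 <- evaluateWithinPanel(X, y, nRepeats = 4, seed = 9, kFolds = 5, grid = g)
  r2 <- evaluateWithinPanel(X, y, nRepeats = 4, seed = 9, kFolds = 5, grid = g)
  expect_identical(accuracies(r1), accuracies(r2))
  r3 <- evaluateWithinPanel(X, y, nRepeats = 4, seed = 9, kFolds = 5,
                            grid = g, splits = attr(r1, "splits"))
  expect_identical(accuracies(r1), accuracies(r3))
})

test_that("cross-panel evaluation stratifies families and excludes overlap", {
  # 25 families x 20 lines; subsets of 10 per family -> 250 training lines
  fam <- rep(sprintf("fam%02d", 1:25), each = 20)
  X <- randX(500, 12, 141)
  set.seed(142)
  beta <- rnorm(12)
  ytr <- as.vector(X %*% beta)
  names(ytr) <- rownames(X)
  famMap <- setNames(fam, rownames(X))
  Xte <- randX(80, 12, 143)
  rownames(Xte) <- paste0("t", seq_len(80))
  colnames(Xte) <- colnames(X)
  yte <- as.vector(Xte %*% beta)
  names(yte) <- rownames(Xte)
  res <- evaluateCrossPanel(X, ytr, Xte, yte, familyMap = famMap,
                            nSubsets = 3, seed = 144, kFolds = 5,
                            grid = 12 * 10^seq(-4, 2, length.out = 10))
  expect_true(all(lengths(attr(res, "subsets")) == 250L))
  expect_length(accuracies(res), 3L)
  expect_gte(meanAccuracy(res), 0.99)
  # identical panels under different names: noise-free transfer is perfect
  Xdup <- X[1:60, ]
  rownames(Xdup) <- paste0("dup", 1:60)
  ydup <- ytr[1:60]
  names(ydup) <- rownames(Xdup)
  res2 <- evaluateCrossPanel(X[1:100, ], ytr[1:100], Xdup, ydup,
                             seed = 145, kFolds = 5,
                             grid = 12 * 10^seq(-4, 2, length.out = 10))
  expect_gte(meanAccuracy(res2), 0.99)
  # overlapping line names are removed from the test side
  expect_message(
    res3 <- evaluateCrossPanel(X[1:100, ], ytr[1:100], X[91:120, ],
                               ytr[91:120], seed = 146, kFolds = 5,
                               grid = 12 * 10^seq(-4, 2, length.out = 10)),
    "overlapping")
  expect_error(evaluateCrossPanel(X, ytr, Xte[, 1:5], yte),
               "feature columns")
})
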