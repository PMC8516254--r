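# Shared fixtures and independent oracles.
# Oracles deliberately use naive dense algebra (solve(), explicit loops),
# not the package's eigendecomposition / Woodbury / SVD code paths.

tinyFounders <- function(nf = 6L, nr = 12L) makeFounders(nf, nr)

tinyPanel <- function(n = 60L, nf = 6L, nr = 12L, blockMean = 4, seed = 1L) {
  simulateDiversePanel(makeFounders(nf, nr), n, blockMean, seed = seed)
}

# one-component REML by dense grid search over the variance ratio
gridRemlRatio <- function(y, H, grid = 10^seq(-4, 4, length.out = 81)) {
  n <- length(y)
  neg2 <- vapply(grid, function(g) {
    V <- g * H + diag(n)
    Vi <- solve(V)
    xvx <- sum(Vi)
    mu <- sum(Vi %*% y) / xvx
    r <- y - mu
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 1)
    as.numeric(determinant(V)$modulus) + log(xvx) + (n - 1) * log(s2)
  }, 0)
  list(ratio = grid[which.min(neg2)], grid = grid,
       which = which.min(neg2))
}

# plain gradient descent on ||yc - Xs b||^2 + lambda ||b||^2
gdRidge <- function(Xs, yc, lambda, iters = 60000L) {
  b <- rep(0, ncol(Xs))
  L <- 2 * (svd(Xs, nu = 0, nv = 0)$d[1]^2 + lambda)
  for (i in seq_len(iters)) {
    gr <- -2 * as.vector(crossprod(Xs, yc - Xs %*% b)) + 2 * lambda * b
    b <- b - gr / L
  }
  b
}

# brute-force trans similarity: count shared haplotypes per line pair
bruteTransHRM <- function(panel) {
  calls <- haplotypeCalls(panel)
  n <- nrow(calls)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- sum(!is.na(calls[i, ]) & !is.na(calls[j, ]) &
                     calls[i, ] == calls[j, ])
  S / (sum(diag(S)) / n)
}

# standardized design exactly as the package builds it
standardizeLike <- function(X, model) {
  sweep(sweep(X[, model$kept, drop = FALSE], 2L, model$center), 2L,
        model$scale, "/")
}
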