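#' @include relationship.R
NULL

asRelMatrix <- function(H) {
  if (is(H, "RelationshipMatrix")) relValues(H) else as.matrix(H)
}

# restricted log-likelihood (full constant included) for V = sum(var_i K_i),
# intercept-only fixed effects; used for reporting and optimality checks
remlLoglik <- function(y, kernels, variances) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (i in seq_along(kernels)) V <- V + variances[i] * kernels[[i]]
  ch <- chol(V)
  logdet <- 2 * sum(log(diag(ch)))
  Viy <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  Vi1 <- backsolve(ch, backsolve(ch, rep(1, n), transpose = TRUE))
  xvx <- sum(Vi1)
  mu <- sum(Viy) / xvx
  quad <- sum((y - mu) * (Viy - mu * Vi1))
  -0.5 * ((n - 1) * log(2 * pi) + logdet + log(xvx) + quad)
}

#' Fit model 1: cis haplotype effects as fixed effects
#'
#' One-way fixed-effects least squares `y = 1 mu + Z alpha + e`. The
#' intercept is the unweighted grand mean of `y` over retained lines;
#' haplotype effects are group means minus the grand mean. Lines with an
#' all-zero design row (missing haplotype call) are dropped; haplotypes with
#' no carriers are dropped.
#'
#' @param y numeric expression vector, aligned with the rows of `Z`.
#' @param Z indicator matrix from [buildDesignMatrix()].
#' @return a [VarCompFit-class] with `effects` holding the per-haplotype
#'   fixed-effect solutions.
#' @examples
#' Z <- matrix(c(1,1,0,0, 0,0,1,1), 4, 2, dimnames = list(NULL, c("1","2")))
#' fitModel1(c(1, 1, 3, 3), Z)
#' @export
fitModel1 <- function(y, Z) {
  keep <- rowSums(Z) > 0 & !is.na(y)
  y <- y[keep]
  Z <- Z[keep, , drop = FALSE]
  Z <- Z[, colSums(Z) > 0, drop = FALSE]
  n <- length(y)
  p <- ncol(Z)
  if (n <= p) stop("saturated model: n <= number of haplotypes")
  mu <- mean(y)
  gm <- as.vector(crossprod(Z, y) / colSums(Z))
  alpha <- gm - mu
  names(alpha) <- colnames(Z)
  fitted <- mu + as.vector(Z %*% alpha)
  rss <- sum((y - fitted)^2)
  s2 <- rss / (n - p)
  ll <- -0.5 * n * (log(2 * pi * max(rss / n, .Machine$double.xmin)) + 1)
  new("VarCompFit", model = 1L, mu = mu, sigma2Cis = NA_real_,
      sigma2Trans = NA_real_, sigma2E = s2, loglik = ll, converged = TRUE,
      nUsed = n, effects = alpha, flags = character())
}

#' Fit model 2: cis haplotype effects as a single random component
#'
#' REML for `y = 1 mu + u_cis + e`, `u_cis ~ N(0, H sigma2_cis)`. The
#' restricted likelihood is profiled over the error variance and maximized
#' over the variance ratio `gamma = sigma2_cis / sigma2_e` on the log scale,
#' using the eigendecomposition of H so each ratio evaluation is O(n).
#'
#' @param y numeric expression vector.
#' @param H a cis [RelationshipMatrix-class] (or plain PSD matrix) aligned
#'   with `y`.
#' @return a [VarCompFit-class] (model 2).
#' @export
fitModel2 <- function(y, H) {
  H <- asRelMatrix(H)
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  if (nrow(H) != n) stop("H not conformable with y")
  eg <- eigen(H, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("H is not positive semi-definite")
  lam <- pmax(eg$values, 0)
  yt <- as.vector(crossprod(eg$vectors, y))
  xt <- as.vector(crossprod(eg$vectors, rep(1, n)))
  neg2 <- function(lg) {
    d <- exp(lg) * lam + 1
    xvx <- sum(xt^2 / d)
    mu <- sum(xt * yt / d) / xvx
    r <- yt - mu * xt
    s2 <- sum(r^2 / d) / (n - 1)
    sum(log(d)) + log(xvx) + (n - 1) * log(max(s2, .Machine$double.xmin))
  }
  lo <- -25; hi <- 25
  opt <- stats::optimize(neg2, c(lo, hi), tol = 1e-10)
  # the profile can be monotone (boundary optimum); check the endpoints
  cand <- c(opt$minimum, lo, hi)
  vals <- c(opt$objective, neg2(lo), neg2(hi))
  lg <- cand[which.min(vals)]
  g <- exp(lg)
  d <- g * lam + 1
  xvx <- sum(xt^2 / d)
  mu <- sum(xt * yt / d) / xvx
  r <- yt - mu * xt
  s2e <- sum(r^2 / d) / (n - 1)
  s2c <- g * s2e
  if (lg <= lo + 1e-6) s2c <- 0
  ll <- -0.5 * (min(vals) + (n - 1) * (log(2 * pi) + 1))
  new("VarCompFit", model = 2L, mu = mu, sigma2Cis = s2c,
      sigma2Trans = NA_real_, sigma2E = s2e, loglik = ll, converged = TRUE,
      nUsed = n, effects = numeric(), flags = character())
}

#' Fit model 3: cis and genome-wide trans random components
#'
#' REML for `y = 1 mu + u_cis + u_trans + e`, with
#' `u_cis ~ N(0, H_cis sigma2_cis)` and `u_trans ~ N(0, H_trans
#' sigma2_trans)`. The restricted likelihood is profiled over the error
#' variance and maximized over the two log variance ratios by Nelder-Mead
#' from multiple starts; each evaluation is one Cholesky factorization.
#' Variances are floored at zero at the parameterization's boundary.
#'
#' @param y numeric expression vector.
#' @param Hcis,Htrans cis and trans [RelationshipMatrix-class] objects (or
#'   plain PSD matrices) aligned with `y`.
#' @param Z optional cis indicator matrix; when supplied (with
#'   `transEigen`) the cis kernel's low rank is exploited through the
#'   Woodbury identity and the trans kernel's eigendecomposition, making
#'   each likelihood evaluation O(n p^2) instead of O(n^3). The two paths
#'   agree to optimizer tolerance.
#' @param transEigen `eigen(Htrans, symmetric = TRUE)`, precomputed once
#'   per panel and shared across genes.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @return a [VarCompFit-class] (model 3). A near-collinear pair of kernels
#'   is flagged `"identifiability"` (the cis/trans split is then poorly
#'   determined although the total genetic variance is).
#' @export
fitModel3 <- function(y, Hcis = NULL, Htrans = NULL, Z = NULL,
                      transEigen = NULL, maxit = 400L) {
  if (!is.null(Z)) {
    if (is.null(transEigen)) {
      if (is.null(Htrans)) stop("supply Htrans or transEigen with Z")
      transEigen <- eigen(asRelMatrix(Htrans), symmetric = TRUE)
    }
    return(fitModel3LowRank(y, Z, transEigen, maxit))
  }
  Hc <- asRelMatrix(Hcis)
  Ht <- asRelMatrix(Htrans)
  n <- length(y)
  if (nrow(Hc) != n || nrow(Ht) != n) stop("kernels not conformable with y")
  if (n < 4L) stop("need at least 4 observations")
  flags <- character()
  oc <- Hc[upper.tri(Hc)]; ot <- Ht[upper.tri(Ht)]
  if (stats::sd(oc) > 0 && stats::sd(ot) > 0 &&
      stats::cor(oc, ot) > 0.99)
    flags <- c(flags, "identifiability")
  one <- rep(1, n)
  I <- diag(n)
  neg2 <- function(par) {
    g <- exp(pmin(pmax(par, -30), 30))
    W <- g[1] * Hc + g[2] * Ht + I
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
    logdet <- 2 * sum(log(diag(ch)))
    Wiy <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
    Wi1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
    xvx <- sum(Wi1)
    mu <- sum(Wiy) / xvx
    quad <- sum((y - mu) * (Wiy - mu * Wi1))
    s2 <- quad / (n - 1)
    logdet + log(xvx) + (n - 1) * log(max(s2, .Machine$double.xmin))
  }
  starts <- list(c(0, 0), c(log(0.1), log(2)), c(log(2), log(0.1)),
                 c(-8, 0), c(0, -8))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, neg2, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- best$convergence == 0
  if (!converged) flags <- c(flags, "non-convergence")
  par <- pmin(pmax(best$par, -30), 30)
  g <- exp(par)
  W <- g[1] * Hc + g[2] * Ht + I
  ch <- chol(W)
  Wiy <- backsolve(ch, backsolve(ch, y, transpose = TRUE))
  Wi1 <- backsolve(ch, backsolve(ch, one, transpose = TRUE))
  xvx <- sum(Wi1)
  mu <- sum(Wiy) / xvx
  s2e <- sum((y - mu) * (Wiy - mu * Wi1)) / (n - 1)
  s2c <- g[1] * s2e
  s2t <- g[2] * s2e
  if (par[1] <= -29) s2c <- 0
  if (par[2] <= -29) s2t <- 0
  ll <- -0.5 * (best$value + (n - 1) * (log(2 * pi) + 1))
  new("VarCompFit", model = 3L, mu = mu, sigma2Cis = s2c, sigma2Trans = s2t,
      sigma2E = s2e, loglik = ll, converged = converged, nUsed = n,
      effects = numeric(), flags = flags)
}

# model-3 REML exploiting rank(Z) << n: rotate into the trans kernel's
# eigenbasis, apply Woodbury to the low-rank cis part; identical restricted
# likelihood as the dense path
fitModel3LowRank <- function(y, Z, transEigen, maxit = 400L) {
  Z <- Z[, colSums(Z) > 0, drop = FALSE]
  n <- length(y)
  p <- ncol(Z)
  lamT <- pmax(transEigen$values, 0)
  U <- transEigen$vectors
  yt <- as.vector(crossprod(U, y))
  xt <- as.vector(crossprod(U, rep(1, n)))
  Zt <- crossprod(U, Z)
  cNorm <- sum(Z^2) / n  # tr(ZZ')/n
  eval3 <- function(par, details = FALSE) {
    g <- exp(pmin(pmax(par, -30), 30))
    A <- g[2] * lamT + 1
    ZtA <- Zt / A
    M <- diag(cNorm / g[1], p) + crossprod(Zt, ZtA)
    chM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(chM)) return(if (details) NULL else 1e12)
    solveW <- function(v) {
      v1 <- v / A
      s <- backsolve(chM, backsolve(chM, crossprod(Zt, v1),
                                    transpose = TRUE))
      v1 - as.vector(ZtA %*% s)
    }
    logdet <- sum(log(A)) + 2 * sum(log(diag(chM))) +
      p * log(g[1] / cNorm)
    Wiy <- solveW(yt)
    Wi1 <- solveW(xt)
    xvx <- sum(xt * Wi1)
    mu <- sum(xt * Wiy) / xvx
    r <- yt - mu * xt
    quad <- sum(r * (Wiy - mu * Wi1))
    s2 <- quad / (n - 1)
    val <- logdet + log(xvx) + (n - 1) * log(max(s2, .Machine$double.xmin))
    if (details) list(value = val, mu = mu, s2e = s2) else val
  }
  starts <- list(c(0, 0), c(log(0.1), log(2)), c(log(2), log(0.1)),
                 c(-8, 0), c(0, -8))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, eval3, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  converged <- best$convergence == 0
  flags <- if (converged) character() else "non-convergence"
  par <- pmin(pmax(best$par, -30), 30)
  g <- exp(par)
  det <- eval3(par, details = TRUE)
  s2e <- det$s2e
  s2c <- if (par[1] <= -29) 0 else g[1] * s2e
  s2t <- if (par[2] <= -29) 0 else g[2] * s2e
  ll <- -0.5 * (det$value + (n - 1) * (log(2 * pi) + 1))
  new("VarCompFit", model = 3L, mu = det$mu, sigma2Cis = s2c,
      sigma2Trans = s2t, sigma2E = s2e, loglik = ll, converged = converged,
      nUsed = n, effects = numeric(), flags = flags)
}

#' Variance decomposition of a model-3 fit
#'
#' h2_cis = sigma2_cis / total, h2_trans = sigma2_trans / total,
#' heritable proportion = (sigma2_cis + sigma2_trans) / total, and the cis
#' share of heritable variance sigma2_cis / (sigma2_cis + sigma2_trans),
#' with total = sigma2_cis + sigma2_trans + sigma2_e.
#'
#' @param fit a model-3 [VarCompFit-class].
#' @return named numeric `c(h2_cis, h2_trans, heritable_prop,
#'   cis_share_of_heritable)`; all `NA` when every variance is zero, and the
#'   cis share `NA` when the heritable part is zero.
#' @examples
#' decomposeVariance(new("VarCompFit", model = 3L, mu = 0, sigma2Cis = 1,
#'   sigma2Trans = 1, sigma2E = 2, loglik = 0, converged = TRUE,
#'   nUsed = 10L, effects = numeric(), flags = character()))
#' @export
decomposeVariance <- function(fit) {
  if (fit@model != 3L) stop("variance decomposition requires a model-3 fit")
  sc <- fit@sigma2Cis; st <- fit@sigma2Trans; se <- fit@sigma2E
  tot <- sc + st + se
  if (!is.finite(tot) || tot <= 0)
    return(c(h2_cis = NA_real_, h2_trans = NA_real_,
             heritable_prop = NA_real_, cis_share_of_heritable = NA_real_))
  gen <- sc + st
  c(h2_cis = sc / tot, h2_trans = st / tot, heritable_prop = gen / tot,
    cis_share_of_heritable = if (gen > 0) sc / gen else NA_real_)
}

#' Partition expression variance gene by gene
#'
#' Runs the chosen per-gene model over (a subset of) the genes of an
#' expression object: builds each gene's cis design matrix and kernel from
#' the panel, reuses one genome-wide trans kernel (model 3), drops lines
#' with a missing haplotype at the focal range, and collects variance
#' components and the model-3 decomposition.
#'
#' @param se expression `SummarizedExperiment` (genes x lines) with a
#'   `range_id` rowData column, e.g. from [simulateExpression()] or
#'   [readExpression()].
#' @param panel the [HaplotypePanel-class] of the same lines.
#' @param model 1, 2 or 3.
#' @param tissue assay name or index (default first assay).
#' @param genes gene IDs to fit (default all).
#' @param transHRM optional precomputed trans [RelationshipMatrix-class];
#'   built from all genic ranges when `NULL` and `model == 3`.
#' @return a `data.frame`, one row per gene: variance components,
#'   decomposition shares, `converged`, `n_used`, `flags`. The fits
#'   themselves are attached as the `"fits"` attribute (a named list).
#' @export
partitionExpression <- function(se, panel, model = 3L, tissue = 1L,
                                genes = NULL, transHRM = NULL) {
  model <- as.integer(model)
  Y <- SummarizedExperiment::assay(se, tissue)
  rd <- SummarizedExperiment::rowData(se)
  if (is.null(rd$range_id)) stop("se must carry a range_id rowData column")
  if (is.null(genes)) genes <- rownames(se)
  lines <- colnames(se)
  if (!all(lines %in% lineIds(panel)))
    stop("expression lines missing from the panel: ",
         paste(utils::head(setdiff(lines, lineIds(panel))), collapse = ", "))
  panel <- panel[lines, ]
  Htrans <- NULL
  egT <- NULL
  if (model == 3L) {
    if (is.null(transHRM)) transHRM <- buildTransHRM(panel)
    Htrans <- relValues(transHRM)[lines, lines]
    egT <- eigen(Htrans, symmetric = TRUE)
  }
  fits <- vector("list", length(genes))
  names(fits) <- genes
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    Z <- buildDesignMatrix(panel, rd[g, "range_id"])
    keep <- rowSums(Z) > 0 & !is.na(Y[g, ])
    y <- Y[g, keep]
    Zk <- Z[keep, colSums(Z[keep, , drop = FALSE]) > 0, drop = FALSE]
    fit <- switch(model,
      fitModel1(y, Zk),
      fitModel2(y, buildHRM(Zk)),
      if (all(keep)) fitModel3(y, Z = Zk, transEigen = egT) else
        fitModel3(y, buildHRM(Zk), Htrans[keep, keep]))
    fits[[i]] <- fit
    dec <- if (model == 3L) decomposeVariance(fit) else
      c(h2_cis = NA_real_, h2_trans = NA_real_, heritable_prop = NA_real_,
        cis_share_of_heritable = NA_real_)
    rows[[i]] <- data.frame(gene_id = g, model = model, mu = fit@mu,
      sigma2_cis = fit@sigma2Cis, sigma2_trans = fit@sigma2Trans,
      sigma2_e = fit@sigma2E, t(dec), loglik = fit@loglik,
      converged = fit@converged, n_used = fit@nUsed,
      flags = paste(fit@flags, collapse = ";"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- genes
  attr(out, "fits") <- fits
  out
}
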