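#' @include methods.R
NULL

# standardize columns; zero-variance columns are dropped with a warning
standardizeFeatures <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep],
              "/")
  list(X = Xs, center = ctr[keep], scale = scl[keep], kept = colnames(X)[keep])
}

#' Ridge solution path over a set of regularization values
#'
#' Solves `argmin_b ||y - Xb||^2 + lambda ||b||^2` in closed form for every
#' `lambda`, on centered, unit-variance features with an unpenalized
#' intercept. One thin SVD of the standardized design serves all lambdas
#' (this is also the n < p dual solution). Coefficients are returned on the
#' original feature scale.
#'
#' @param X numeric matrix, lines x features (column names required).
#' @param y numeric response.
#' @param lambdas non-negative regularization values.
#' @return list with `beta` (features x lambdas, original scale),
#'   `intercept` (per lambda), `lambdas`, and the standardization
#'   parameters (`center`, `scale`, `kept`).
#' @seealso [fitRidge()], [selectLambdaCV()]
#' @export
ridgePath <- function(X, y, lambdas) {
  if (any(lambdas < 0)) stop("lambda must be >= 0")
  if (nrow(X) < 3L) stop("need at least 3 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  st <- standardizeFeatures(X)
  ybar <- mean(y)
  yc <- y - ybar
  sv <- svd(st$X)
  keepd <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keepd]
  Uy <- as.vector(crossprod(sv$u[, keepd, drop = FALSE], yc))
  betaStd <- vapply(lambdas, function(l) {
    as.vector(sv$v[, keepd, drop = FALSE] %*% (d * Uy / (d^2 + l)))
  }, numeric(ncol(st$X)))
  betaStd <- matrix(betaStd, ncol = length(lambdas))
  beta <- betaStd / st$scale
  rownames(beta) <- st$kept
  intercept <- ybar - as.vector(crossprod(beta, st$center))
  list(beta = beta, intercept = intercept, lambdas = lambdas,
       center = st$center, scale = st$scale, kept = st$kept)
}

#' Fit a ridge-regression model
#'
#' Closed-form ridge fit of `||y - Xb||^2 + lambda ||b||^2` (standardized
#' features, unpenalized intercept); see [ridgePath()].
#'
#' @param X numeric matrix, lines x features.
#' @param y numeric response.
#' @param lambda a single regularization value (> 0 in routine use; 0
#'   permitted and solved by pseudo-inverse).
#' @return an object of class `"RidgeModel"`: list with `beta`, `intercept`,
#'   `lambda` and standardization parameters; use [predict()] on new data.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- X[, 1] + rnorm(20, sd = 0.1)
#' m <- fitRidge(X, y, lambda = 1)
#' cor(predict(m, X), y)
#' @export
fitRidge <- function(X, y, lambda) {
  if (length(lambda) != 1L) stop("lambda must be a single value")
  p <- ridgePath(X, y, lambda)
  structure(list(beta = p$beta[, 1L], intercept = p$intercept[1L],
                 lambda = lambda, center = p$center, scale = p$scale,
                 kept = p$kept),
            class = "RidgeModel")
}

#' Predict from a RidgeModel
#' @param object a `"RidgeModel"` from [fitRidge()].
#' @param newdata matrix of features (must contain the fitted columns).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.RidgeModel <- function(object, newdata, ...) {
  as.vector(newdata[, object$kept, drop = FALSE] %*% object$beta) +
    object$intercept
}

defaultLambdaGrid <- function(X, length.out = 100L) {
  # log-spaced grid scaled by tr(X'X)/n of the standardized design (= p)
  ncol(X) * 10^seq(-4, 4, length.out = length.out)
}

#' Select the ridge penalty by k-fold cross-validation
#'
#' Chooses the `lambda` minimizing the mean held-out squared error over
#' `kFolds` folds. Ties are resolved toward the larger (more shrinking)
#' `lambda`, and by default a tie is any value whose CV error is within one
#' standard error (over folds) of the minimum -- the resolution of the CV
#' estimate itself. On a pure-noise response the error curve is flat at its
#' minimum once shrinkage is complete, so this picks heavy shrinkage; with
#' `oneSE = FALSE` only exact numerical ties count. Standardization is
#' redone inside every fold from its training part only.
#'
#' @param X numeric matrix, lines x features.
#' @param y numeric response.
#' @param grid candidate lambdas; default 100 log-spaced values spanning
#'   `[1e-4, 1e4] * p` (p = number of features, the scale of `tr(X'X)/n`
#'   after standardization).
#' @param kFolds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param oneSE treat every lambda within one standard error of the
#'   minimum as tied with it (default `TRUE`).
#' @return the selected lambda, with the CV error curve attached as
#'   attribute `"cvMse"`.
#' @export
selectLambdaCV <- function(X, y, grid = NULL, kFolds = 10L, seed = 1L,
                           oneSE = TRUE) {
  n <- nrow(X)
  if (n < kFolds) stop("n < kFolds")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.null(grid)) grid <- defaultLambdaGrid(X)
  if (!length(grid)) stop("empty lambda grid")
  grid <- sort(grid)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(kFolds), n))
  sse <- matrix(NA_real_, kFolds, length(grid))
  for (f in seq_len(kFolds)) {
    tr <- fold != f
    path <- ridgePath(X[tr, , drop = FALSE], y[tr], grid)
    pred <- X[!tr, path$kept, drop = FALSE] %*% path$beta
    pred <- sweep(pred, 2L, path$intercept, "+")
    sse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  mse <- colMeans(sse)
  tol <- if (oneSE) {
    i <- which.min(mse)
    stats::sd(sse[, i]) / sqrt(kFolds)
  } else min(mse) * 1e-12
  best <- which(mse <= min(mse) + tol)
  lam <- grid[max(best)]
  attr(lam, "cvMse") <- stats::setNames(mse, signif(grid, 6))
  lam
}

#' Pearson prediction accuracy
#'
#' The Pearson correlation between observed and predicted trait values. A
#' constant observed or predicted vector makes the correlation undefined:
#' `NA` is returned with a warning so evaluation protocols can exclude the
#' repeat.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return Pearson r, or `NA` if undefined.
#' @examples
#' predictionAccuracy(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
predictionAccuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3L) stop("need at least 3 pairs")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("constant vector: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}
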