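#' @include ridge.R
NULL

# expand one master seed into a reproducible table of sub-seeds
expandSeed <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Within-panel prediction accuracy by Monte Carlo cross-validation
#'
#' Repeated random sub-sampling validation: the panel is split into a
#' training fraction and a test fraction `nRepeats` times; in every repeat
#' the ridge penalty is re-selected by k-fold cross-validation on the
#' training part only, the model is refit, and the test-set Pearson
#' accuracy recorded. A constant test response makes that repeat's accuracy
#' `NA` (excluded from the mean).
#'
#' @param X numeric matrix, lines x features.
#' @param y named numeric trait vector aligned with `rownames(X)`.
#' @param nRepeats number of random partitions (default 20).
#' @param trainFrac training fraction (default 0.8).
#' @param seed master seed; expands deterministically into per-repeat split
#'   and fold seeds.
#' @param grid,kFolds passed to [selectLambdaCV()].
#' @param trait,featureKind labels stored in the result.
#' @param splits optional list of training-index vectors overriding the
#'   random splits (used to evaluate permuted features on identical
#'   partitions).
#' @return a [PredictionResult-class]; its `"splits"` attribute records the
#'   training indices actually used.
#' @export
evaluateWithinPanel <- function(X, y, nRepeats = 20L, trainFrac = 0.8,
                                seed = 1L, grid = NULL, kFolds = 10L,
                                trait = "trait", featureKind = "HARE",
                                splits = NULL) {
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 lines")
  if (!is.null(names(y))) y <- y[rownames(X)]
  seeds <- expandSeed(seed, 2L * nRepeats)
  splitSeeds <- seeds[seq_len(nRepeats)]
  foldSeeds <- seeds[nRepeats + seq_len(nRepeats)]
  if (is.null(splits)) {
    splits <- lapply(splitSeeds, function(s) {
      set.seed(s)
      sort(sample.int(n, round(trainFrac * n)))
    })
  }
  acc <- lam <- rep(NA_real_, nRepeats)
  for (i in seq_len(nRepeats)) {
    tr <- splits[[i]]
    l <- selectLambdaCV(X[tr, , drop = FALSE], y[tr], grid = grid,
                        kFolds = kFolds, seed = foldSeeds[i])
    m <- fitRidge(X[tr, , drop = FALSE], y[tr], as.numeric(l))
    yhat <- predict(m, X[-tr, , drop = FALSE])
    acc[i] <- if (stats::sd(y[-tr]) == 0) NA_real_ else
      stats::cor(y[-tr], yhat)
    lam[i] <- as.numeric(l)
  }
  res <- new("PredictionResult", accuracies = acc, protocol = "within",
             trait = trait, featureKind = featureKind, lambdas = lam)
  attr(res, "splits") <- splits
  res
}

#' Cross-panel prediction accuracy
#'
#' Trains ridge models in one panel and tests in another sharing the same
#' feature columns. With a `familyMap` (NAM-style training panel),
#' `nSubsets` stratified training subsets are drawn -- `perFamily` lines per
#' family -- and the test accuracy is averaged over subsets; without one, a
#' single train/test run is performed. Lines present in both panels (e.g.
#' founders) are removed from the test set first.
#'
#' @param Xtrain,ytrain training features and trait.
#' @param Xtest,ytest test features and trait (columns must match
#'   `Xtrain`).
#' @param familyMap optional factor/character named by training line giving
#'   each line's family.
#' @param perFamily lines sampled per family per subset (default 10; a
#'   smaller family is sampled at its size with a warning).
#' @param nSubsets number of stratified subsets (default 20).
#' @param seed master seed.
#' @param grid,kFolds passed to [selectLambdaCV()].
#' @param trait,featureKind labels stored in the result.
#' @param subsets optional list of training-line-index vectors overriding
#'   the stratified sampling (for permutation reuse).
#' @return a [PredictionResult-class] with one accuracy per subset (or a
#'   single accuracy); attribute `"subsets"` records the indices used.
#' @export
evaluateCrossPanel <- function(Xtrain, ytrain, Xtest, ytest,
                               familyMap = NULL, perFamily = 10L,
                               nSubsets = 20L, seed = 1L, grid = NULL,
                               kFolds = 10L, trait = "trait",
                               featureKind = "HARE", subsets = NULL) {
  if (!identical(colnames(Xtrain), colnames(Xtest)))
    stop("feature columns differ between panels")
  overlap <- intersect(rownames(Xtrain), rownames(Xtest))
  if (length(overlap)) {
    message("removing ", length(overlap), " overlapping line(s) from the test set")
    keep <- !(rownames(Xtest) %in% overlap)
    Xtest <- Xtest[keep, , drop = FALSE]
    ytest <- ytest[keep]
  }
  if (!is.null(names(ytrain))) ytrain <- ytrain[rownames(Xtrain)]
  if (!is.null(names(ytest))) ytest <- ytest[rownames(Xtest)]
  seeds <- expandSeed(seed, 2L * max(nSubsets, 1L))
  if (is.null(familyMap) && is.null(subsets)) {
    l <- selectLambdaCV(Xtrain, ytrain, grid = grid, kFolds = kFolds,
                        seed = seeds[1L])
    m <- fitRidge(Xtrain, ytrain, as.numeric(l))
    acc <- predictionAccuracy(ytest, predict(m, Xtest))
    res <- new("PredictionResult", accuracies = acc, protocol = "cross",
               trait = trait, featureKind = featureKind,
               lambdas = as.numeric(l))
    attr(res, "subsets") <- list(seq_len(nrow(Xtrain)))
    return(res)
  }
  if (is.null(subsets)) {
    fam <- familyMap[rownames(Xtrain)]
    famIdx <- split(seq_len(nrow(Xtrain)), fam)
    short <- names(famIdx)[lengths(famIdx) < perFamily]
    if (length(short))
      warning("families smaller than perFamily sampled at their size: ",
              paste(short, collapse = ", "))
    subsets <- lapply(seq_len(nSubsets), function(i) {
      set.seed(seeds[i])
      sort(unlist(lapply(famIdx, function(ix)
        sample(ix, min(perFamily, length(ix))))))
    })
  }
  acc <- lam <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    ix <- subsets[[i]]
    l <- selectLambdaCV(Xtrain[ix, , drop = FALSE], ytrain[ix], grid = grid,
                        kFolds = kFolds, seed = seeds[nSubsets + i])
    m <- fitRidge(Xtrain[ix, , drop = FALSE], ytrain[ix], as.numeric(l))
    acc[i] <- predictionAccuracy(ytest, predict(m, Xtest))
    lam[i] <- as.numeric(l)
  }
  res <- new("PredictionResult", accuracies = acc, protocol = "cross",
             trait = trait, featureKind = featureKind, lambdas = lam)
  attr(res, "subsets") <- subsets
  res
}
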