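#' @include evaluate.R
#' @include hare.R
NULL

#' Haplotype-structure-preserving permutation of a HareMatrix
#'
#' For every gene independently, the haplotype-to-effect map is shuffled
#' uniformly over the haplotypes present in that gene's universe, so each
#' gene keeps exactly the same multiset of effect values but the values are
#' randomly re-matched to haplotypes ("random HARE"). Lines sharing a
#' haplotype still receive identical imputed values afterwards. Genes with a
#' single haplotype are left unchanged.
#'
#' @param hare a [HareMatrix-class].
#' @param seed RNG seed.
#' @return a [HareMatrix-class] of the same shape.
#' @export
permuteHare <- function(hare, seed = 1L) {
  eff <- hare@effects
  prov <- hare@provenance
  set.seed(as.integer(seed))
  for (g in seq_len(nrow(eff))) {
    present <- which(!is.na(prov[g, ]))
    if (length(present) < 2L) next
    perm <- sample(present)
    eff[g, present] <- eff[g, perm]
    prov[g, present] <- prov[g, perm]
  }
  new("HareMatrix", effects = eff, mu = hare@mu, provenance = prov,
      model = hare@model, tissue = hare@tissue, rangeIds = hare@rangeIds)
}

#' Monte Carlo permutation p-value
#'
#' `p = (r + 1) / (k + 1)`, where `k` is the number of permutations and `r`
#' counts permutations whose accuracy is at least the observed one (high
#' tail) or at most the observed one (low tail). Ties count toward `r`, and
#' the smallest attainable p-value is `1 / (k + 1)`.
#'
#' @param observed observed accuracy (scalar).
#' @param permuted numeric vector of k permuted accuracies.
#' @param tail `"high"` (permutations beating the observed value) or
#'   `"low"`.
#' @return p-value in `[1/(k+1), 1]`.
#' @examples
#' mcPvalue(0.9, rep(0.1, 100))          # 1/101
#' mcPvalue(0.1, rep(0.9, 100))          # 1
#' @export
mcPvalue <- function(observed, permuted, tail = c("high", "low")) {
  tail <- match.arg(tail)
  permuted <- permuted[!is.na(permuted)]
  k <- length(permuted)
  if (k < 1L) stop("empty permutation set")
  r <- if (tail == "high") sum(permuted >= observed) else
    sum(permuted <= observed)
  (r + 1) / (k + 1)
}

#' Significance of HARE's prediction accuracy over random HARE
#'
#' Runs the full random-HARE baseline: the observed HareMatrix is imputed
#' into the evaluation panel and its mean prediction accuracy computed under
#' the chosen protocol; then `k` independently permuted HareMatrices are
#' pushed through the *identical* protocol -- the same train/test
#' partitions, subset draws and fold seeds -- and the Monte Carlo p-values
#' `(r+1)/(k+1)` are reported for both tails.
#'
#' @param hare a [HareMatrix-class].
#' @param panel evaluation [HaplotypePanel-class] (within-panel protocol)
#'   or the training panel (cross-panel protocol).
#' @param phenotype named numeric trait for the lines of `panel`.
#' @param k number of permutations (default 100).
#' @param seed master seed; expands into the evaluation seed and one
#'   permutation seed per replicate.
#' @param protocol `"within"` or `"cross"`.
#' @param testPanel,testPhenotype test panel and trait (cross protocol).
#' @param familyMap family map for stratified training subsets (cross
#'   protocol, optional).
#' @param ... further arguments to [evaluateWithinPanel()] /
#'   [evaluateCrossPanel()] (`nRepeats`, `grid`, `kFolds`, ...).
#' @return a list of class `"PermutationOutcome"`: `observed`
#'   ([PredictionResult-class]), `observedMean`, `permutedMeans` (length
#'   k), `pHigh`, `pLow`, `k`.
#' @export
runPermutationStudy <- function(hare, panel, phenotype, k = 100L, seed = 1L,
                                protocol = c("within", "cross"),
                                testPanel = NULL, testPhenotype = NULL,
                                familyMap = NULL, ...) {
  protocol <- match.arg(protocol)
  if (k < 1L) stop("k must be >= 1")
  seeds <- expandSeed(seed, k + 1L)
  evalSeed <- seeds[1L]
  permSeeds <- seeds[-1L]
  runOne <- function(hm, splits = NULL, subsets = NULL) {
    if (protocol == "within") {
      X <- imputeExpression(hm, panel)
      evaluateWithinPanel(X, phenotype, seed = evalSeed, splits = splits,
                          featureKind = "HARE", ...)
    } else {
      Xtr <- imputeExpression(hm, panel)
      Xte <- imputeExpression(hm, testPanel)
      evaluateCrossPanel(Xtr, phenotype, Xte, testPhenotype,
                         familyMap = familyMap, seed = evalSeed,
                         subsets = subsets, featureKind = "HARE", ...)
    }
  }
  obs <- runOne(hare)
  splits <- attr(obs, "splits")
  subsets <- attr(obs, "subsets")
  permMeans <- vapply(seq_len(k), function(i) {
    ph <- permuteHare(hare, seed = permSeeds[i])
    meanAccuracy(runOne(ph, splits = splits, subsets = subsets))
  }, 0)
  obsMean <- meanAccuracy(obs)
  structure(list(observed = obs, observedMean = obsMean,
                 permutedMeans = permMeans,
                 pHigh = mcPvalue(obsMean, permMeans, "high"),
                 pLow = mcPvalue(obsMean, permMeans, "low"), k = k),
            class = "PermutationOutcome")
}

#' @export
print.PermutationOutcome <- function(x, ...) {
  cat(sprintf(
    "PermutationOutcome: observed mean accuracy %.4f over %d permutations\n",
    x$observedMean, x$k))
  cat(sprintf("  permuted mean %.4f (sd %.4f); p_high = %.4g, p_low = %.4g\n",
              mean(x$permutedMeans), stats::sd(x$permutedMeans), x$pHigh,
              x$pLow))
  invisible(x)
}
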