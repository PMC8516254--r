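#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors metadata
NULL

#' HaplotypePanel: founder-haplotype assignments over genic reference ranges
#'
#' A panel of inbred lines genotyped as one integer haplotype ID per line per
#' reference range. Lines are fully homozygous, so a single ID per cell
#' suffices; missing assignments are `NA`. Reference ranges are carried as a
#' [GenomicRanges::GRanges] whose names are the range identifiers and which
#' has a logical `genic` metadata column.
#'
#' @slot calls integer matrix, lines x ranges; rownames are line IDs,
#'   colnames are range IDs; `NA` marks a missing haplotype assignment.
#' @slot ranges `GRanges` of the reference ranges, names matching
#'   `colnames(calls)`, with a `genic` metadata column.
#'
#' @seealso [simulateNamPanel()], [simulateDiversePanel()],
#'   [buildDesignMatrix()], [panelSummary()]
#' @export
setClass("HaplotypePanel",
  representation(calls = "matrix", ranges = "GRanges"))

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  if (!is.integer(object@calls) && !all(is.na(object@calls)))
    msg <- c(msg, "calls must be an integer matrix")
  if (is.null(rownames(object@calls)))
    msg <- c(msg, "calls must have line IDs as rownames")
  if (anyDuplicated(rownames(object@calls)))
    msg <- c(msg, "duplicated line IDs")
  if (is.null(colnames(object@calls)))
    msg <- c(msg, "calls must have range IDs as colnames")
  if (length(object@ranges) != ncol(object@calls))
    msg <- c(msg, "number of ranges does not match number of call columns")
  if (!identical(names(object@ranges), colnames(object@calls)))
    msg <- c(msg, "range names must match call colnames in order")
  if (anyDuplicated(names(object@ranges)))
    msg <- c(msg, "duplicated range IDs")
  if (length(msg)) msg else TRUE
})

#' RelationshipMatrix: trace-normalized haplotype similarity between lines
#'
#' Symmetric positive semi-definite n x n matrix H = ZZ' / (tr(ZZ')/n) built
#' from haplotype indicator matrices, so that trace(H) = n. `kind` records
#' whether the kernel is the cis kernel of a single reference range or the
#' trans kernel combined over many ranges.
#'
#' @slot values numeric n x n matrix with line IDs as dimnames.
#' @slot kind character, `"cis"` or `"trans"`.
#' @slot rangeId character, the focal range for a cis kernel (`NA` for trans).
#'
#' @seealso [buildHRM()], [buildTransHRM()]
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", kind = "character", rangeId = "character"))

setValidity("RelationshipMatrix", function(object) {
  H <- object@values
  msg <- character()
  if (nrow(H) != ncol(H)) msg <- c(msg, "matrix must be square")
  if (!isSymmetric(unname(H), tol = 1e-8)) msg <- c(msg, "matrix must be symmetric")
  if (abs(sum(diag(H)) - nrow(H)) > 1e-6 * nrow(H))
    msg <- c(msg, "trace must equal n (trace-normalized)")
  if (!object@kind %in% c("cis", "trans")) msg <- c(msg, "kind must be 'cis' or 'trans'")
  if (length(msg)) msg else TRUE
})

#' VarCompFit: per-gene variance-component solution
#'
#' The fit of one of the three per-gene expression models: model 1 treats cis
#' haplotype effects as fixed, model 2 as random, model 3 adds a genome-wide
#' trans random component. Variance components are REML estimates (models 2
#' and 3) or the residual variance of the least-squares fit (model 1).
#'
#' @slot model integer 1, 2 or 3.
#' @slot mu numeric intercept (grand mean for model 1, GLS mean otherwise).
#' @slot sigma2Cis,sigma2Trans,sigma2E numeric variance components (>= 0;
#'   `NA` where the model has no such component).
#' @slot loglik numeric restricted log-likelihood at the optimum (model 1:
#'   profile log-likelihood of the residual variance).
#' @slot converged logical.
#' @slot nUsed integer count of lines retained in the fit.
#' @slot effects named numeric, fixed haplotype effects (model 1 only,
#'   empty otherwise); names are haplotype IDs.
#' @slot flags character vector of fit diagnostics (e.g. identifiability
#'   warnings).
#'
#' @seealso [fitModel1()], [fitModel2()], [fitModel3()], [decomposeVariance()]
#' @export
setClass("VarCompFit",
  representation(model = "integer", mu = "numeric", sigma2Cis = "numeric",
    sigma2Trans = "numeric", sigma2E = "numeric", loglik = "numeric",
    converged = "logical", nUsed = "integer", effects = "numeric",
    flags = "character"))

setValidity("VarCompFit", function(object) {
  msg <- character()
  if (!object@model %in% 1:3) msg <- c(msg, "model must be 1, 2 or 3")
  for (s in c("sigma2Cis", "sigma2Trans", "sigma2E")) {
    v <- slot(object, s)
    if (length(v) == 1L && !is.na(v) && v < 0) msg <- c(msg, paste(s, "must be >= 0"))
  }
  if (object@model == 1L && !is.na(object@sigma2Trans))
    msg <- c(msg, "model 1 has no trans component")
  if (object@model == 2L && !is.na(object@sigma2Trans))
    msg <- c(msg, "model 2 has no trans component")
  if (length(msg)) msg else TRUE
})

#' HareMatrix: per-gene, per-haplotype cis expression effects
#'
#' Gene x haplotype table of estimated cis haplotype associated RNA
#' expression (HARE) effects, stored relative to the per-gene intercept.
#' Haplotypes of the universe that were not observed in the training panel
#' receive the gene's mean estimated effect (mean imputation) and are flagged
#' in `provenance`. Cells that are `NA` in both slots are haplotypes outside
#' that gene's universe.
#'
#' @slot effects numeric matrix, genes x haplotypes; rownames gene IDs,
#'   colnames haplotype IDs (as character).
#' @slot mu named numeric, per-gene intercept on the expression scale.
#' @slot provenance character matrix, same shape as `effects`, entries
#'   `"estimated"`, `"imputed"` or `NA`.
#' @slot model integer, the model the effects came from.
#' @slot tissue character tissue tag (may be `NA`).
#' @slot rangeIds named character, the reference range hosting each gene
#'   (names = gene IDs); used to look haplotypes up in a target panel.
#'
#' @seealso [estimateHare()], [buildHareMatrix()], [imputeExpression()],
#'   [permuteHare()]
#' @export
setClass("HareMatrix",
  representation(effects = "matrix", mu = "numeric", provenance = "matrix",
    model = "integer", tissue = "character", rangeIds = "character"))

setValidity("HareMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@effects), dim(object@provenance)))
    msg <- c(msg, "effects and provenance must have identical dimensions")
  if (!identical(rownames(object@effects), names(object@mu)))
    msg <- c(msg, "mu must be named by the effect rownames")
  est <- !is.na(object@provenance)
  if (any(is.na(object@effects[est])))
    msg <- c(msg, "flagged cells must carry an effect value")
  if (length(object@rangeIds) &&
      !identical(names(object@rangeIds), rownames(object@effects)))
    msg <- c(msg, "rangeIds must be named by the effect rownames")
  if (length(msg)) msg else TRUE
})

#' PredictionResult: accuracy of one genomic-prediction evaluation
#'
#' Holds the per-repeat Pearson accuracies of a ridge-regression prediction
#' protocol (within-panel Monte Carlo cross-validation or cross-panel
#' transfer), together with the protocol and feature metadata.
#'
#' @slot accuracies numeric vector of per-repeat Pearson correlations
#'   between observed and predicted trait values (`NA` where a test split was
#'   degenerate).
#' @slot protocol character, `"within"` or `"cross"`.
#' @slot trait character trait label.
#' @slot featureKind character, e.g. `"HARE"`, `"measured"`, `"SNP"`.
#' @slot lambdas numeric, the regularization value selected in each repeat.
#'
#' @seealso [evaluateWithinPanel()], [evaluateCrossPanel()]
#' @export
setClass("PredictionResult",
  representation(accuracies = "numeric", protocol = "character",
    trait = "character", featureKind = "character", lambdas = "numeric"))

setValidity("PredictionResult", function(object) {
  a <- object@accuracies
  if (any(!is.na(a) & (a < -1 - 1e-12 | a > 1 + 1e-12)))
    "accuracies must lie in [-1, 1]" else TRUE
})
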