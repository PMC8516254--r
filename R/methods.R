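#' @include AllGenerics.R
NULL

#' Construct a HaplotypePanel
#'
#' @param calls integer matrix of haplotype IDs, lines x ranges, with line
#'   IDs as rownames and range IDs as colnames; `NA` marks missing calls.
#' @param ranges a `GRanges` named by range ID (same order as the call
#'   columns) or `NULL` to synthesize consecutive 1 kb ranges on a single
#'   linear chromosome `"chr1"`.
#' @return a [HaplotypePanel-class] object.
#' @examples
#' calls <- matrix(c(1L, 1L, 2L, 2L), 4, 1,
#'                 dimnames = list(paste0("L", 1:4), "r1"))
#' HaplotypePanel(calls)
#' @export
HaplotypePanel <- function(calls, ranges = NULL) {
  storage.mode(calls) <- "integer"
  if (is.null(ranges)) {
    p <- ncol(calls)
    ranges <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(start = seq_len(p) * 1000L - 999L, width = 1000L),
      genic = rep(TRUE, p))
    names(ranges) <- colnames(calls)
  }
  new("HaplotypePanel", calls = calls, ranges = ranges)
}

#' @rdname lineIds
#' @export
setMethod("lineIds", "HaplotypePanel", function(x) rownames(x@calls))

#' @rdname rangeIds
#' @export
setMethod("rangeIds", "HaplotypePanel", function(x) colnames(x@calls))

#' @rdname haplotypeCalls
#' @export
setMethod("haplotypeCalls", "HaplotypePanel", function(x) x@calls)

#' @rdname refRanges
#' @export
setMethod("refRanges", "HaplotypePanel", function(x) x@ranges)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel with", nrow(object@calls), "lines and",
      ncol(object@calls), "reference ranges\n")
  nh <- length(unique(as.vector(object@calls[!is.na(object@calls)])))
  cat("  distinct haplotype IDs:", nh,
      "| missing calls:", sum(is.na(object@calls)), "\n")
})

#' Subset a HaplotypePanel by lines and/or ranges
#'
#' @param x a `HaplotypePanel`.
#' @param i line selector (indices, logicals or line IDs).
#' @param j range selector.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", "HaplotypePanel", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  rng <- x@ranges
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  if (!missing(j)) {
    calls <- calls[, j, drop = FALSE]
    rng <- rng[j]
  }
  new("HaplotypePanel", calls = calls, ranges = rng)
})

#' @rdname relValues
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)

#' @rdname lineIds
#' @export
setMethod("lineIds", "RelationshipMatrix", function(x) rownames(x@values))

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix (%s%s): %d x %d, trace = %.4f\n",
    object@kind,
    if (object@kind == "cis" && !is.na(object@rangeId))
      paste0(", range ", object@rangeId) else "",
    nrow(object@values), ncol(object@values), sum(diag(object@values))))
})

#' @rdname varComponents
#' @export
setMethod("varComponents", "VarCompFit", function(x)
  c(mu = x@mu, sigma2_cis = x@sigma2Cis, sigma2_trans = x@sigma2Trans,
    sigma2_e = x@sigma2E))

setMethod("show", "VarCompFit", function(object) {
  cat(sprintf("VarCompFit (model %d, n = %d, %sconverged)\n", object@model,
      object@nUsed, if (object@converged) "" else "NOT "))
  v <- varComponents(object)
  cat("  ", paste(sprintf("%s = %.4g", names(v), v), collapse = ", "), "\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

#' @rdname hareEffects
#' @export
setMethod("hareEffects", "HareMatrix", function(x) x@effects)

#' @rdname hareIntercepts
#' @export
setMethod("hareIntercepts", "HareMatrix", function(x) x@mu)

#' @rdname provenance
#' @export
setMethod("provenance", "HareMatrix", function(x) x@provenance)

setMethod("show", "HareMatrix", function(object) {
  pr <- object@provenance
  cat(sprintf("HareMatrix: %d genes x %d haplotypes (model %d%s)\n",
      nrow(object@effects), ncol(object@effects), object@model,
      if (!is.na(object@tissue)) paste0(", tissue ", object@tissue) else ""))
  cat(sprintf("  cells: %d estimated, %d mean-imputed\n",
      sum(pr == "estimated", na.rm = TRUE), sum(pr == "imputed", na.rm = TRUE)))
})

#' @rdname accuracies
#' @export
setMethod("accuracies", "PredictionResult", function(x) x@accuracies)

#' @rdname meanAccuracy
#' @export
setMethod("meanAccuracy", "PredictionResult", function(x, na.rm = TRUE)
  mean(x@accuracies, na.rm = na.rm))

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s-panel, trait '%s', features %s)\n",
      object@protocol, object@trait, object@featureKind))
  cat(sprintf("  %d repeats, mean accuracy %.4f (sd %.4f)\n",
      length(object@accuracies), meanAccuracy(object),
      stats::sd(object@accuracies, na.rm = TRUE)))
})
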