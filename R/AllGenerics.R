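#' @include AllClasses.R
NULL

#' Line identifiers of an object
#' @param x a `HaplotypePanel` or `RelationshipMatrix`.
#' @return character vector of line IDs.
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' Reference-range identifiers of a panel
#' @param x a `HaplotypePanel`.
#' @return character vector of range IDs, in genome order.
#' @export
setGeneric("rangeIds", function(x) standardGeneric("rangeIds"))

#' Haplotype call matrix of a panel
#' @param x a `HaplotypePanel`.
#' @return integer matrix, lines x ranges, `NA` = missing.
#' @export
setGeneric("haplotypeCalls", function(x) standardGeneric("haplotypeCalls"))

#' Reference ranges of a panel
#' @param x a `HaplotypePanel`.
#' @return a `GRanges`, names = range IDs, with a `genic` column.
#' @export
setGeneric("refRanges", function(x) standardGeneric("refRanges"))

#' Numeric matrix inside a RelationshipMatrix
#' @param x a `RelationshipMatrix`.
#' @return the n x n numeric matrix.
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))

#' Variance components of a fit
#' @param x a `VarCompFit`.
#' @return named numeric `c(mu, sigma2_cis, sigma2_trans, sigma2_e)`
#'   (`NA` for components absent from the model).
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' Effect table of a HareMatrix
#' @param x a `HareMatrix`.
#' @return numeric matrix genes x haplotypes.
#' @export
setGeneric("hareEffects", function(x) standardGeneric("hareEffects"))

#' Per-gene intercepts of a HareMatrix
#' @param x a `HareMatrix`.
#' @return named numeric vector.
#' @export
setGeneric("hareIntercepts", function(x) standardGeneric("hareIntercepts"))

#' Provenance flags of a HareMatrix
#' @param x a `HareMatrix`.
#' @return character matrix (`"estimated"` / `"imputed"` / `NA`).
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Per-repeat accuracies of a prediction result
#' @param x a `PredictionResult`.
#' @return numeric vector.
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' Mean accuracy of a prediction result
#' @param x a `PredictionResult`.
#' @param na.rm drop degenerate repeats before averaging (default `TRUE`).
#' @return numeric scalar, the mean Pearson accuracy over repeats.
#' @export
setGeneric("meanAccuracy", function(x, na.rm = TRUE) standardGeneric("meanAccuracy"))
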