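#' @include methods.R
NULL

#' Haplotype indicator (design) matrix for one reference range
#'
#' Builds the n x p 0/1 indicator matrix Z over the haplotypes observed at a
#' range: row i has a 1 in the column of line i's haplotype. Lines with a
#' missing call get an all-zero row (flagged in the `"missingLines"`
#' attribute); columns are ordered by ascending haplotype ID and columns
#' that would be all zero are dropped.
#'
#' @param panel a [HaplotypePanel-class].
#' @param rangeId a range ID present in the panel.
#' @return numeric matrix with line IDs as rownames and haplotype IDs (as
#'   character) as colnames; attribute `missingLines` lists lines with no
#'   call at the range.
#' @examples
#' calls <- matrix(c(1L, 1L, 2L, 2L), 4, 1,
#'                 dimnames = list(paste0("L", 1:4), "r1"))
#' buildDesignMatrix(HaplotypePanel(calls), "r1")
#' @export
buildDesignMatrix <- function(panel, rangeId) {
  calls <- haplotypeCalls(panel)
  if (!rangeId %in% colnames(calls))
    stop("unknown range: ", rangeId)
  h <- calls[, rangeId]
  if (all(is.na(h))) stop("range ", rangeId, " has no haplotype calls")
  haps <- sort(unique(h[!is.na(h)]))
  Z <- matrix(0, length(h), length(haps),
              dimnames = list(names(h), as.character(haps)))
  ok <- !is.na(h)
  Z[cbind(which(ok), match(h[ok], haps))] <- 1
  attr(Z, "missingLines") <- names(h)[!ok]
  Z
}

#' Trace-normalized haplotype relationship matrix
#'
#' H = ZZ' / (tr(ZZ')/n), so trace(H) = n. With 0/1 indicators this is the
#' proportion-of-shared-haplotypes similarity rescaled to an average
#' diagonal of 1.
#'
#' @param Z indicator matrix from [buildDesignMatrix()] (or any numeric
#'   matrix with >= 1 column).
#' @param kind `"cis"` or `"trans"`.
#' @param rangeId focal range label for a cis kernel.
#' @return a [RelationshipMatrix-class].
#' @export
buildHRM <- function(Z, kind = "cis", rangeId = NA_character_) {
  if (ncol(Z) < 1L) stop("Z must have at least one column")
  if (nrow(Z) < 2L) stop("need at least 2 lines")
  ZZt <- tcrossprod(Z)
  tr <- sum(diag(ZZt))
  if (tr <= 0) stop("zero trace: all design rows are zero")
  H <- ZZt / (tr / nrow(Z))
  dimnames(H) <- list(rownames(Z), rownames(Z))
  new("RelationshipMatrix", values = H, kind = kind, rangeId = rangeId)
}

#' Genome-wide trans haplotype relationship matrix
#'
#' Column-concatenates the per-range haplotype indicators over the supplied
#' genic ranges and trace-normalizes the resulting ZZ'. By default all
#' supplied ranges enter, including any focal gene's own range; set
#' `excludeRange` to obtain the leave-one-range-out variant.
#'
#' @param panel a [HaplotypePanel-class].
#' @param rangeIds ranges to combine (default: all ranges flagged genic).
#' @param excludeRange optional range ID to leave out.
#' @return a [RelationshipMatrix-class] of kind `"trans"`.
#' @export
buildTransHRM <- function(panel, rangeIds = NULL, excludeRange = NULL) {
  if (is.null(rangeIds)) {
    rng <- refRanges(panel)
    genic <- S4Vectors::mcols(rng)$genic
    rangeIds <- names(rng)[if (is.null(genic)) TRUE else genic]
  }
  rangeIds <- setdiff(rangeIds, excludeRange)
  if (length(rangeIds) < 2L) stop("need at least 2 ranges for a trans kernel")
  Z <- do.call(cbind, lapply(rangeIds, function(r) buildDesignMatrix(panel, r)))
  buildHRM(Z, kind = "trans")
}

#' Plug-in Shannon entropy of haplotype counts
#'
#' Maximum-likelihood (plug-in) estimator -sum p ln p in nats, with p the
#' observed haplotype frequencies; zero-count categories are ignored.
#'
#' @param counts non-negative counts (named or not), summing to > 0.
#' @return entropy in nats.
#' @examples
#' haplotypeEntropy(c(2500, rep(100, 25)))  # idealized NAM design: 2.3026
#' haplotypeEntropy(rep(1, 8))              # ln 8
#' @export
haplotypeEntropy <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("counts must sum to > 0")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Per-range haplotype counts, entropy and panel-wide summaries
#'
#' Tabulates haplotype counts at every range, computes the per-range plug-in
#' Shannon entropy, and reports the panel-wide median haplotype frequency
#' (median over all (range, haplotype) count entries) and median entropy.
#'
#' @param panel a [HaplotypePanel-class].
#' @return a list: `counts` (named list of per-range count tables),
#'   `entropy` (named numeric per range, nats), `medianFrequency`,
#'   `medianEntropy`.
#' @export
panelSummary <- function(panel) {
  calls <- haplotypeCalls(panel)
  if (nrow(calls) < 1L) stop("empty panel")
  counts <- lapply(colnames(calls), function(r) table(calls[, r], useNA = "no"))
  names(counts) <- colnames(calls)
  entropy <- vapply(counts, function(ct) haplotypeEntropy(as.numeric(ct)), 0)
  allFreq <- unlist(lapply(counts, as.numeric), use.names = FALSE)
  list(counts = counts, entropy = entropy,
       medianFrequency = stats::median(allFreq),
       medianEntropy = stats::median(entropy))
}
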