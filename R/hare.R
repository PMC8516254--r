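#' @include varcomp.R
NULL

#' Per-haplotype cis expression effects from a fitted gene model
#'
#' Model 1 returns the fixed-effect solutions directly. Models 2 and 3
#' return per-haplotype BLUPs via the projection
#' `a_hat = sigma2_a Z' V^-1 (y - 1 mu_hat)` with
#' `sigma2_a = sigma2_cis / c`, `c = tr(ZZ')/n`, and `V` the fitted marginal
#' covariance; this is the unique haplotype-level vector whose line-level
#' image satisfies `u_cis = Z a_hat` under `H_cis = ZZ'/c`.
#'
#' @param fit a [VarCompFit-class] for the gene.
#' @param Z the gene's indicator matrix (same lines as the fit, all-zero
#'   rows and empty columns removed beforehand).
#' @param y the expression vector used in the fit.
#' @param Htrans trans kernel matrix (model 3 only), aligned with `y`.
#' @return named numeric vector of per-haplotype effects (relative to the
#'   intercept), with attribute `ucis` = the line-level cis genetic values
#'   `Z %*% a_hat`.
#' @export
estimateHare <- function(fit, Z, y, Htrans = NULL) {
  Z <- Z[, colSums(Z) > 0, drop = FALSE]
  n <- nrow(Z)
  if (length(y) != n) stop("y and Z are not conformable")
  if (fit@model == 1L) {
    a <- fit@effects[colnames(Z)]
    names(a) <- colnames(Z)
  } else {
    cNorm <- sum(Z^2) / n  # tr(ZZ') for 0/1 Z
    s2c <- fit@sigma2Cis
    if (s2c <= 0) {
      a <- stats::setNames(rep(0, ncol(Z)), colnames(Z))
    } else {
      V <- s2c * tcrossprod(Z) / cNorm + fit@sigma2E * diag(n)
      if (fit@model == 3L) {
        if (is.null(Htrans)) stop("model 3 requires the trans kernel")
        V <- V + fit@sigma2Trans * asRelMatrix(Htrans)
      }
      ch <- tryCatch(chol(V), error = function(e) {
        chol(V + diag(n) * 1e-8 * mean(diag(V)))
      })
      r <- y - fit@mu
      Vir <- backsolve(ch, backsolve(ch, r, transpose = TRUE))
      a <- as.vector((s2c / cNorm) * crossprod(Z, Vir))
      names(a) <- colnames(Z)
    }
  }
  structure(a, ucis = as.vector(Z %*% a))
}

#' Assemble a HareMatrix with mean imputation of unobserved haplotypes
#'
#' Collects per-gene haplotype effects into a gene x haplotype matrix over a
#' common haplotype universe. Haplotypes of the universe without an estimate
#' for a gene receive that gene's mean estimated effect and are flagged
#' `"imputed"`; genes with no estimates at all are excluded with a message.
#'
#' @param effectsList named list (by gene) of named numeric effect vectors
#'   (names = haplotype IDs).
#' @param universe character (or integer) vector of all haplotype IDs the
#'   matrix should cover; default the union of estimated haplotypes.
#' @param mu named numeric per-gene intercepts (aligned with
#'   `names(effectsList)`).
#' @param rangeIds named character, the reference range of each gene.
#' @param model integer model tag.
#' @param tissue character tissue tag.
#' @return a [HareMatrix-class].
#' @export
buildHareMatrix <- function(effectsList, universe = NULL, mu = NULL,
                            rangeIds = character(), model = 3L,
                            tissue = NA_character_) {
  ok <- vapply(effectsList, function(e) length(e) > 0, TRUE)
  if (any(!ok))
    message("excluding ", sum(!ok), " gene(s) with no estimated haplotypes")
  effectsList <- effectsList[ok]
  if (!length(effectsList)) stop("no genes with estimated effects")
  genes <- names(effectsList)
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(effectsList, names))))
  universe <- as.character(universe)
  eff <- matrix(NA_real_, length(genes), length(universe),
                dimnames = list(genes, universe))
  prov <- matrix(NA_character_, length(genes), length(universe),
                 dimnames = list(genes, universe))
  for (g in genes) {
    e <- effectsList[[g]]
    known <- intersect(names(e), universe)
    eff[g, known] <- e[known]
    prov[g, known] <- "estimated"
    unseen <- setdiff(universe, known)
    if (length(unseen)) {
      eff[g, unseen] <- mean(e[known])
      prov[g, unseen] <- "imputed"
    }
  }
  if (is.null(mu)) mu <- stats::setNames(rep(0, length(genes)), genes)
  mu <- mu[genes]
  if (length(rangeIds)) rangeIds <- rangeIds[genes]
  new("HareMatrix", effects = eff, mu = mu, provenance = prov,
      model = as.integer(model), tissue = tissue, rangeIds = rangeIds)
}

#' Estimate a HareMatrix from an expression panel
#'
#' Convenience driver over the whole transcriptome: fits the chosen model
#' gene by gene ([partitionExpression()]), extracts per-haplotype effects
#' ([estimateHare()]) and assembles the [HareMatrix-class] with mean
#' imputation over `universe`.
#'
#' @inheritParams partitionExpression
#' @param universe haplotype universe for [buildHareMatrix()]; default all
#'   haplotype IDs observed anywhere in the panel.
#' @return a [HareMatrix-class].
#' @export
hareFromExpression <- function(se, panel, model = 3L, tissue = 1L,
                               genes = NULL, transHRM = NULL,
                               universe = NULL) {
  model <- as.integer(model)
  Y <- SummarizedExperiment::assay(se, tissue)
  rd <- SummarizedExperiment::rowData(se)
  if (is.null(genes)) genes <- rownames(se)
  lines <- colnames(se)
  panel <- panel[lines, ]
  if (is.null(universe)) {
    calls <- haplotypeCalls(panel)
    universe <- sort(unique(as.vector(calls[!is.na(calls)])))
  }
  Htrans <- NULL
  egT <- NULL
  if (model == 3L) {
    if (is.null(transHRM)) transHRM <- buildTransHRM(panel)
    Htrans <- relValues(transHRM)[lines, lines]
    egT <- eigen(Htrans, symmetric = TRUE)
  }
  effectsList <- vector("list", length(genes))
  names(effectsList) <- genes
  mu <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (g in genes) {
    Z <- buildDesignMatrix(panel, rd[g, "range_id"])
    keep <- rowSums(Z) > 0 & !is.na(Y[g, ])
    y <- Y[g, keep]
    Zk <- Z[keep, colSums(Z[keep, , drop = FALSE]) > 0, drop = FALSE]
    fit <- switch(model,
      fitModel1(y, Zk),
      fitModel2(y, buildHRM(Zk)),
      if (all(keep)) fitModel3(y, Z = Zk, transEigen = egT) else
        fitModel3(y, buildHRM(Zk), Htrans[keep, keep]))
    effectsList[[g]] <- estimateHare(fit, Zk, y,
      Htrans = if (model == 3L) Htrans[keep, keep] else NULL)
    attr(effectsList[[g]], "ucis") <- NULL
    mu[g] <- fit@mu
  }
  tisName <- if (is.character(tissue)) tissue else
    SummarizedExperiment::assayNames(se)[tissue]
  rng <- stats::setNames(as.character(rd[genes, "range_id"]), genes)
  buildHareMatrix(effectsList, universe = universe, mu = mu, rangeIds = rng,
                  model = model, tissue = tisName)
}

#' Impute HARE values into a target panel
#'
#' `value(line, gene) = mu_g + effect(gene, haplotype(line, gene))`. Lines
#' with a missing haplotype call at a gene receive `mu_g` plus the gene's
#' mean estimated effect. A haplotype outside the HareMatrix universe is an
#' error naming the offending (line, range) pairs. The result is a
#' deterministic function of its two inputs.
#'
#' @param hare a [HareMatrix-class] (must carry `rangeIds`).
#' @param target a [HaplotypePanel-class] sharing the haplotype universe.
#' @return numeric matrix, target lines x genes, on the expression scale;
#'   attributes `tissue` and `model` copied from `hare`.
#' @export
imputeExpression <- function(hare, target) {
  if (!length(hare@rangeIds))
    stop("HareMatrix carries no gene-to-range map")
  calls <- haplotypeCalls(target)
  genes <- rownames(hare@effects)
  universe <- colnames(hare@effects)
  out <- matrix(NA_real_, nrow(calls), length(genes),
                dimnames = list(rownames(calls), genes))
  bad <- character()
  for (g in genes) {
    r <- hare@rangeIds[g]
    if (!r %in% colnames(calls)) stop("target panel lacks range ", r)
    h <- as.character(calls[, r])
    known <- is.na(h) | h %in% universe
    if (any(!known))
      bad <- c(bad, paste0(rownames(calls)[!known], "@", r, "=", h[!known]))
    e <- hare@effects[g, ]
    est <- hare@provenance[g, ] == "estimated"
    meanEff <- mean(e[which(est)])
    v <- rep(NA_real_, length(h))
    v[known & !is.na(h)] <- e[h[known & !is.na(h)]]
    v[is.na(h)] <- meanEff
    # haplotype inside the universe but outside this gene's universe
    v[known & is.na(v)] <- meanEff
    out[, g] <- hare@mu[g] + v
  }
  if (length(bad))
    stop("haplotypes outside the HARE universe: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  attr(out, "tissue") <- hare@tissue
  attr(out, "model") <- hare@model
  out
}

#' Integrate expression matrices across tissues
#'
#' Element-wise mean or maximum over identically shaped per-tissue matrices.
#'
#' @param matrices list of numeric matrices with identical dimnames.
#' @param mode `"mean"` or `"max"`.
#' @return a single matrix of the same shape.
#' @export
integrateTissues <- function(matrices, mode = c("mean", "max")) {
  mode <- match.arg(mode)
  if (!length(matrices)) stop("no matrices supplied")
  dn <- dimnames(matrices[[1L]])
  for (m in matrices)
    if (!identical(dimnames(m), dn))
      stop("tissue matrices must share identical dimnames")
  if (length(matrices) == 1L) return(matrices[[1L]])
  A <- array(unlist(matrices), dim = c(dim(matrices[[1L]]), length(matrices)))
  out <- if (mode == "mean") apply(A, c(1, 2), mean) else
    apply(A, c(1, 2), max)
  dimnames(out) <- dn
  out
}

# per-gene Pearson correlation across shared lines of two line x gene
# matrices; zero-variance genes come back NA
pairwiseGeneCorrelation <- function(A, B) {
  genes <- intersect(colnames(A), colnames(B))
  lines <- intersect(rownames(A), rownames(B))
  if (length(lines) < 3L) stop("need at least 3 shared lines")
  r <- vapply(genes, function(g) {
    a <- A[lines, g]; b <- B[lines, g]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
      stats::cor(a, b)
  }, 0)
  names(r) <- genes
  r
}

#' Cross-tissue transferability correlations
#'
#' Enumerates all unordered pairs of tissues and computes, for each pair,
#' the per-gene Pearson correlation across lines, summarizing each pair by
#' its median. Applied to measured expression and to imputed HARE values it
#' quantifies how much more transferable the cis component is across
#' tissues.
#'
#' @param matrices named list of line x gene matrices, one per tissue.
#' @return a list: `pairs` (data.frame tissue1, tissue2, median_r, n_genes),
#'   `perGene` (genes x pairs matrix of correlations), `medianOverall`.
#' @export
crossTissueCorrelation <- function(matrices) {
  k <- length(matrices)
  if (k < 2L) stop("need at least 2 tissues")
  if (is.null(names(matrices))) names(matrices) <- paste0("tissue", seq_len(k))
  cmb <- utils::combn(names(matrices), 2L)
  cols <- vector("list", ncol(cmb))
  for (j in seq_len(ncol(cmb)))
    cols[[j]] <- pairwiseGeneCorrelation(matrices[[cmb[1L, j]]],
                                         matrices[[cmb[2L, j]]])
  perGene <- do.call(cbind, cols)
  colnames(perGene) <- apply(cmb, 2L, paste, collapse = ":")
  pairs <- data.frame(tissue1 = cmb[1L, ], tissue2 = cmb[2L, ],
    median_r = apply(perGene, 2L, stats::median, na.rm = TRUE),
    n_genes = apply(perGene, 2L, function(x) sum(!is.na(x))))
  list(pairs = pairs, perGene = perGene,
       medianOverall = stats::median(perGene, na.rm = TRUE))
}

#' Correlation between HARE-imputed and measured expression
#'
#' Per-gene Pearson correlation across lines between a HARE-imputed matrix
#' and measured expression, plus the median over genes.
#'
#' @param imputed line x gene matrix from [imputeExpression()].
#' @param measured line x gene matrix of measured expression (transpose an
#'   assay if needed).
#' @return a list: `perGene` (named numeric), `median`.
#' @export
hareVsMeasuredCorrelation <- function(imputed, measured) {
  r <- pairwiseGeneCorrelation(imputed, measured)
  list(perGene = r, median = stats::median(r, na.rm = TRUE))
}
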