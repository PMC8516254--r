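#' @include methods.R
NULL

#' Founder haplotype set
#'
#' Creates the founder panel that seeds all simulations: `nFounders` inbred
#' founders, each carrying one distinct haplotype ID per reference range.
#' Haplotype IDs are the founder index (1..nFounders), so every range has the
#' same universe of founder haplotypes and any panel derived from these
#' founders shares that universe. One founder is designated the common
#' parent of the NAM design.
#'
#' @param nFounders number of founders (default 26, mirroring a maize NAM
#'   founder set plus common parent).
#' @param nRanges number of genic reference ranges on the single linear
#'   simulated genome.
#' @param commonParent line ID of the designated common parent (default the
#'   first founder).
#' @return a [HaplotypePanel-class] of the founders; the common parent is
#'   recorded in `metadata(refRanges(x))$commonParent`.
#' @examples
#' f <- makeFounders(nFounders = 4, nRanges = 10)
#' haplotypeCalls(f)[, 1:3]
#' @export
makeFounders <- function(nFounders = 26L, nRanges, commonParent = NULL) {
  if (nFounders < 1L || nRanges < 1L)
    stop("nFounders and nRanges must be positive")
  ids <- sprintf("F%02d", seq_len(nFounders))
  if (is.null(commonParent)) commonParent <- ids[1L]
  if (!commonParent %in% ids) stop("commonParent must be one of the founders")
  calls <- matrix(rep(seq_len(nFounders), nRanges), nrow = nFounders,
                  dimnames = list(ids, sprintf("r%04d", seq_len(nRanges))))
  storage.mode(calls) <- "integer"
  panel <- HaplotypePanel(calls)
  S4Vectors::metadata(panel@ranges)$commonParent <- commonParent
  panel
}

commonParentOf <- function(founders) {
  cp <- S4Vectors::metadata(refRanges(founders))$commonParent
  if (is.null(cp)) rownames(haplotypeCalls(founders))[1L] else cp
}

#' Simulate a NAM-design RIL panel
#'
#' Emulates a nested association mapping design: `nFamilies` biparental
#' families, each the cross of one non-common founder with the shared common
#' parent, selfed to fully homozygous recombinant inbred lines (RILs). Each
#' RIL carries, at every reference range, either the common parent's or its
#' family parent's haplotype. Recombination is a two-state Markov chain along
#' the ordered ranges with per-adjacent-range switch probability
#' `crossoversPerRangeSet / (nRanges - 1)` (capped at 0.5); the marginal
#' probability of either parent at any range is 1/2.
#'
#' @param founders founder panel from [makeFounders()].
#' @param nFamilies number of biparental families (<= nFounders - 1).
#' @param rilsPerFamily RILs per family.
#' @param crossoversPerRangeSet expected number of parental switches along
#'   the whole range sequence per RIL (default 10).
#' @param seed integer RNG seed.
#' @return a [HaplotypePanel-class] of `nFamilies * rilsPerFamily` RILs;
#'   line IDs encode the family (`fam03_ril012`).
#' @examples
#' f <- makeFounders(6, 20)
#' nam <- simulateNamPanel(f, nFamilies = 5, rilsPerFamily = 10, seed = 1)
#' nam
#' @export
simulateNamPanel <- function(founders, nFamilies, rilsPerFamily,
                             crossoversPerRangeSet = 10, seed = 1L) {
  fc <- haplotypeCalls(founders)
  cp <- commonParentOf(founders)
  others <- setdiff(rownames(fc), cp)
  if (nFamilies > length(others))
    stop("nFamilies exceeds the number of non-common founders")
  if (nFamilies < 1L || rilsPerFamily < 1L)
    stop("nFamilies and rilsPerFamily must be positive")
  p <- ncol(fc)
  s <- if (p > 1L) min(0.5, crossoversPerRangeSet / (p - 1L)) else 0
  if (s < 0) stop("crossoversPerRangeSet must be >= 0")
  n <- nFamilies * rilsPerFamily
  set.seed(as.integer(seed))
  # state 0 = common parent, 1 = family parent; symmetric switching keeps
  # the marginal at 1/2 given a fair start
  start <- stats::rbinom(n, 1L, 0.5)
  state <- matrix(0L, n, p)
  state[, 1L] <- start
  if (p > 1L) {
    switches <- matrix(stats::rbinom(n * (p - 1L), 1L, s), n, p - 1L)
    state <- (start + cbind(0L, t(apply(switches, 1L, cumsum)))) %% 2L
  }
  fam <- rep(seq_len(nFamilies), each = rilsPerFamily)
  parentRow <- fc[others[fam], , drop = FALSE]
  commonRow <- matrix(fc[cp, ], n, p, byrow = TRUE)
  calls <- ifelse(state == 1L, parentRow, commonRow)
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("fam%02d_ril%03d", fam,
                             rep(seq_len(rilsPerFamily), nFamilies))
  colnames(calls) <- colnames(fc)
  HaplotypePanel(calls, refRanges(founders))
}

#' Simulate a diverse mosaic panel
#'
#' Each line is a mosaic of founder haplotypes along the ordered ranges:
#' block lengths are geometric with mean `mosaicBlockMean` ranges, and at
#' each block start a founder is drawn uniformly. This is a structural
#' stand-in for a diverse association panel whose lines are founder-haplotype
#' mosaics, not a population-genetic model of any particular panel.
#'
#' @param founders founder panel from [makeFounders()].
#' @param nLines number of lines to generate.
#' @param mosaicBlockMean mean block length in ranges (>= 1).
#' @param seed integer RNG seed.
#' @return a [HaplotypePanel-class] of `nLines` mosaic lines.
#' @examples
#' f <- makeFounders(6, 30)
#' div <- simulateDiversePanel(f, nLines = 20, mosaicBlockMean = 5, seed = 1)
#' @export
simulateDiversePanel <- function(founders, nLines, mosaicBlockMean = 10,
                                 seed = 1L) {
  if (nLines < 1L) stop("nLines must be >= 1")
  if (mosaicBlockMean < 1) stop("mosaicBlockMean must be >= 1")
  fc <- haplotypeCalls(founders)
  nf <- nrow(fc)
  p <- ncol(fc)
  q <- 1 / mosaicBlockMean
  set.seed(as.integer(seed))
  calls <- matrix(0L, nLines, p)
  for (i in seq_len(nLines)) {
    brk <- c(TRUE, stats::runif(p - 1L) < q)
    block <- cumsum(brk)
    donors <- sample.int(nf, max(block), replace = TRUE)
    f <- donors[block]
    calls[i, ] <- fc[cbind(f, seq_len(p))]
  }
  rownames(calls) <- sprintf("div%04d", seq_len(nLines))
  colnames(calls) <- colnames(fc)
  HaplotypePanel(calls, refRanges(founders))
}

#' Simulation scenario for expression
#'
#' Bundles the variance-structure targets of the expression simulator. The
#' defaults pin the cis share of heritable variance at 1/3 and the heritable
#' proportion at 0.55, the regime the estimators are designed for in diverse
#' maize panels.
#'
#' @param nGenes number of genes (each gene occupies one reference range).
#' @param cisShare target sigma2_cis / (sigma2_cis + sigma2_trans), in [0,1].
#' @param heritability target (sigma2_cis + sigma2_trans) / total variance,
#'   in [0,1].
#' @param nTissues number of tissues to simulate.
#' @param transTissueCorr correlation of trans effects between tissues
#'   (cis effects are fully shared across tissues), in [-1,1].
#' @param traitNoise default noise level for [simulatePhenotype()], as the
#'   ratio of noise SD to genetic-signal SD.
#' @param seed integer RNG seed.
#' @return a named list of class `"SimScenario"`.
#' @export
simScenario <- function(nGenes = 100L, cisShare = 1 / 3, heritability = 0.55,
                        nTissues = 1L, transTissueCorr = 0, traitNoise = 0.5,
                        seed = 1L) {
  stopifnot(nGenes >= 1L, nTissues >= 1L, traitNoise >= 0)
  if (cisShare < 0 || cisShare > 1) stop("cisShare must be in [0, 1]")
  if (heritability < 0 || heritability > 1)
    stop("heritability must be in [0, 1]")
  if (abs(transTissueCorr) > 1) stop("transTissueCorr must be in [-1, 1]")
  structure(list(nGenes = as.integer(nGenes), cisShare = cisShare,
                 heritability = heritability, nTissues = as.integer(nTissues),
                 transTissueCorr = transTissueCorr, traitNoise = traitNoise,
                 seed = as.integer(seed)),
            class = "SimScenario")
}

# center x and rescale to exact sample variance v (returns zeros if x is
# constant)
scaleToVar <- function(x, v) {
  x <- x - mean(x)
  s2 <- sum(x^2) / (length(x) - 1L)
  if (s2 < .Machine$double.eps || v <= 0) return(rep(0, length(x)))
  x * sqrt(v / s2)
}

#' Simulate multi-tissue expression on a panel
#'
#' Generates, for each gene and tissue, `y = mu_g + Z_g a_g + w_t + e`:
#' per-haplotype cis effects `a_g` shared across tissues, a polygenic trans
#' value `w_t` built from a random projection of the haplotype indicators at
#' all other genes (correlated `transTissueCorr` across tissues), and iid
#' noise. Each realized component is rescaled to the scenario's exact target
#' variance (cis: `cisShare * heritability`; trans:
#' `(1 - cisShare) * heritability`; error: `1 - heritability`), so realized
#' variance shares match the scenario by construction. Genes with fewer than
#' two distinct haplotypes in the panel get zero cis variance and are
#' flagged.
#'
#' @param panel a [HaplotypePanel-class]; the first `nGenes` ranges host one
#'   gene each (`nGenes <= ` number of ranges).
#' @param scenario a [simScenario()] object.
#' @return a [SummarizedExperiment::SummarizedExperiment] (genes x lines)
#'   with one assay per tissue; `rowData` carries `range_id` and the
#'   `cis_flagged` indicator; `metadata(se)$truth` is the generative ledger
#'   (per-gene `mu`, haplotype effects `a`, line-level cis values, per-tissue
#'   trans values) and `metadata(se)$scenario` the scenario.
#' @examples
#' f <- makeFounders(6, 25)
#' pan <- simulateDiversePanel(f, 40, 5, seed = 2)
#' se <- simulateExpression(pan, simScenario(nGenes = 20, seed = 3))
#' se
#' @export
simulateExpression <- function(panel, scenario = simScenario()) {
  calls <- haplotypeCalls(panel)
  n <- nrow(calls)
  if (n < 2L) stop("panel must have at least 2 lines")
  G <- scenario$nGenes
  if (G > ncol(calls))
    stop("scenario has more genes than the panel has ranges")
  geneRanges <- colnames(calls)[seq_len(G)]
  geneIds <- paste0("g_", geneRanges)
  nT <- scenario$nTissues
  h2 <- scenario$heritability
  vC <- scenario$cisShare * h2
  vT <- (1 - scenario$cisShare) * h2
  vE <- 1 - h2
  rho <- scenario$transTissueCorr

  set.seed(scenario$seed)
  mu <- stats::rnorm(G, mean = 8, sd = 2)
  names(mu) <- geneIds

  # per-gene cis effects and line-level cis values, rescaled to exact vC
  aList <- vector("list", G)
  cisVal <- matrix(0, n, G, dimnames = list(rownames(calls), geneIds))
  flagged <- logical(G)
  for (g in seq_len(G)) {
    h <- calls[, geneRanges[g]]
    ok <- !is.na(h)
    haps <- sort(unique(h[ok]))
    a <- stats::rnorm(length(haps))
    names(a) <- as.character(haps)
    if (length(haps) < 2L || vC <= 0) {
      flagged[g] <- length(haps) < 2L
      aList[[g]] <- a * 0
      next
    }
    cv <- rep(0, n)
    cv[ok] <- a[as.character(h[ok])]
    m <- mean(cv[ok]); s2 <- stats::var(cv[ok])
    if (s2 < .Machine$double.eps) { flagged[g] <- TRUE; aList[[g]] <- a * 0; next }
    k <- sqrt(vC / s2)
    aList[[g]] <- (a - m) * k
    cv[ok] <- (cv[ok] - m) * k
    cisVal[, g] <- cv
  }
  names(aList) <- geneIds

  # trans values: random projection of all genes' haplotype indicators,
  # focal gene excluded by subtracting its own contribution
  Zlist <- lapply(geneRanges, function(r) {
    h <- calls[, r]
    haps <- sort(unique(h[!is.na(h)]))
    Z <- outer(h, haps, function(a, b) as.numeric(!is.na(a) & a == b))
    Z
  })
  totCols <- sum(vapply(Zlist, ncol, 1L))
  # one shared weight vector plus one per tissue
  B <- matrix(stats::rnorm(totCols * (nT + 1L)), totCols, nT + 1L)
  Zfull <- do.call(cbind, Zlist)
  Tfull <- Zfull %*% B
  colOff <- cumsum(c(0L, vapply(Zlist, ncol, 1L)))

  transVal <- lapply(seq_len(nT), function(t)
    matrix(0, n, G, dimnames = list(rownames(calls), geneIds)))
  for (g in seq_len(G)) {
    idx <- (colOff[g] + 1L):colOff[g + 1L]
    Tg <- Tfull - Zlist[[g]] %*% B[idx, , drop = FALSE]
    shared <- scaleToVar(Tg[, 1L], 1)
    for (t in seq_len(nT)) {
      spec <- scaleToVar(Tg[, t + 1L], 1)
      w <- sqrt(abs(rho)) * sign(rho + (rho == 0)) * shared +
        sqrt(1 - abs(rho)) * spec
      transVal[[t]][, g] <- scaleToVar(w, vT)
    }
  }

  assays <- vector("list", nT)
  for (t in seq_len(nT)) {
    E <- matrix(stats::rnorm(n * G), n, G)
    E <- apply(E, 2L, scaleToVar, v = vE)
    Y <- sweep(cisVal + transVal[[t]] + E, 2L, mu, "+")
    assays[[t]] <- t(Y)  # genes x lines
  }
  names(assays) <- sprintf("tissue%02d", seq_len(nT))
  names(transVal) <- names(assays)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(gene_id = geneIds, range_id = geneRanges,
                                   cis_flagged = flagged, row.names = geneIds),
    colData = S4Vectors::DataFrame(row.names = rownames(calls)))
  S4Vectors::metadata(se)$truth <- list(mu = mu, a = aList, cis = cisVal,
                                        trans = transVal,
                                        targets = c(cis = vC, trans = vT,
                                                    error = vE))
  S4Vectors::metadata(se)$scenario <- scenario
  se
}

#' Simulate a trait driven by cis expression
#'
#' Builds a trait as a weighted sum of the true line-level cis genetic values
#' of randomly chosen causal genes, plus Gaussian noise with SD
#' `traitNoise` times the SD of the genetic signal. When a `panel` other
#' than the training panel is supplied, the causal genes' true haplotype
#' effects are re-applied to that panel's haplotypes, so the same genetic
#' architecture is expressed in any panel sharing the founder haplotypes
#' (the cross-panel prediction setting).
#'
#' @param se expression object from [simulateExpression()] (its `truth`
#'   ledger supplies the effects).
#' @param nCausalGenes number of causal genes.
#' @param traitNoise noise SD relative to the genetic-signal SD; overrides
#'   the scenario default when non-`NULL`.
#' @param seed integer RNG seed.
#' @param panel optional target [HaplotypePanel-class]; default the training
#'   panel implied by `se`.
#' @param causal optional causal architecture (`$genes`, `$coefficients`)
#'   from a previous call, reused verbatim so the same trait can be realized
#'   on a second panel.
#' @return a list: `trait` (named numeric, per line), `genetic` (noise-free
#'   genetic values), `causal` (list with `genes` and `coefficients`),
#'   `heritableFraction` (realized var(genetic)/var(trait)).
#' @export
simulatePhenotype <- function(se, nCausalGenes = 10L, traitNoise = NULL,
                              seed = 1L, panel = NULL, causal = NULL) {
  truth <- S4Vectors::metadata(se)$truth
  scen <- S4Vectors::metadata(se)$scenario
  if (is.null(truth)) stop("se must come from simulateExpression()")
  if (is.null(traitNoise)) traitNoise <- scen$traitNoise
  geneIds <- names(truth$a)
  if (nCausalGenes > length(geneIds))
    stop("nCausalGenes exceeds the number of simulated genes")
  set.seed(as.integer(seed))
  if (is.null(causal)) {
    genes <- sample(geneIds, nCausalGenes)
    coefs <- stats::rnorm(nCausalGenes)
    names(coefs) <- genes
    causal <- list(genes = genes, coefficients = coefs)
  }
  if (is.null(panel)) {
    genetic <- as.vector(truth$cis[, causal$genes, drop = FALSE] %*%
                           causal$coefficients[causal$genes])
    names(genetic) <- rownames(truth$cis)
  } else {
    calls <- haplotypeCalls(panel)
    rd <- SummarizedExperiment::rowData(se)
    genetic <- rep(0, nrow(calls))
    names(genetic) <- rownames(calls)
    for (g in causal$genes) {
      r <- rd[g, "range_id"]
      a <- truth$a[[g]]
      h <- as.character(calls[, r])
      v <- a[h]
      v[is.na(v)] <- 0  # haplotype unseen in training: no cis deviation
      genetic <- genetic + causal$coefficients[g] * v
    }
  }
  sdg <- stats::sd(genetic)
  noise <- stats::rnorm(length(genetic), sd = traitNoise * sdg)
  trait <- genetic + noise
  list(trait = trait, genetic = genetic, causal = causal,
       heritableFraction = if (stats::var(trait) > 0)
         stats::var(genetic) / stats::var(trait) else NA_real_)
}
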