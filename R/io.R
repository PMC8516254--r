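#' @include methods.R
NULL

#' Write / read a haplotype panel as TSV (+ BED ranges)
#'
#' The panel is serialized long-form as a three-column TSV
#' (`line_id`, `range_id`, `haplotype_id`; missing calls written as `NA`),
#' and its reference ranges as BED (0-based, half-open; the `name` field is
#' the range ID). Write-then-read round trips are lossless.
#'
#' @param panel a [HaplotypePanel-class].
#' @param file TSV path.
#' @param bedFile optional BED path for the ranges (written/read when
#'   non-`NULL`; requires the rtracklayer package).
#' @return `writeHaplotypePanel`: invisibly, the file path.
#'   `readHaplotypePanel`: a [HaplotypePanel-class].
#' @export
writeHaplotypePanel <- function(panel, file, bedFile = NULL) {
  calls <- haplotypeCalls(panel)
  long <- data.frame(
    line_id = rep(rownames(calls), times = ncol(calls)),
    range_id = rep(colnames(calls), each = nrow(calls)),
    haplotype_id = as.vector(calls))
  utils::write.table(long, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedFile)) writeRangesBed(refRanges(panel), bedFile)
  invisible(file)
}

#' @rdname writeHaplotypePanel
#' @export
readHaplotypePanel <- function(file, bedFile = NULL) {
  long <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("line_id", "range_id", "haplotype_id")
  if (!all(need %in% names(long)))
    stop("haplotype TSV must have columns ", paste(need, collapse = ", "),
         " (file ", file, ")")
  lines <- unique(long$line_id)
  rangesIds <- unique(long$range_id)
  calls <- matrix(NA_integer_, length(lines), length(rangesIds),
                  dimnames = list(lines, rangesIds))
  calls[cbind(match(long$line_id, lines), match(long$range_id, rangesIds))] <-
    as.integer(long$haplotype_id)
  rng <- if (!is.null(bedFile)) readRangesBed(bedFile)[rangesIds] else NULL
  HaplotypePanel(calls, rng)
}

#' Write / read reference ranges as BED
#'
#' BED convention: 0-based, half-open; the `name` field carries the range
#' ID. All imported ranges are marked genic.
#'
#' @param ranges a `GRanges` named by range ID.
#' @param file BED path.
#' @return `readRangesBed`: a named `GRanges` with a `genic` column.
#' @export
writeRangesBed <- function(ranges, file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED I/O")
  gr <- ranges
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = names(gr))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname writeRangesBed
#' @export
readRangesBed <- function(file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required for BED I/O")
  gr <- rtracklayer::import(file, format = "BED")
  names(gr) <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(genic = rep(TRUE, length(gr)))
  gr
}

# read a lines x columns numeric TSV with row names in the first column;
# any non-numeric cell is an error naming the cell
readNumericTsv <- function(file, what = "matrix") {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (is.character(m)) {
    suppress <- suppressWarnings(mode(m) <- "numeric")
    bad <- which(is.na(m) & !is.na(as.matrix(df[, -1L, drop = FALSE])),
                 arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric ", what, " cell at row '", rn[bad[1L, 1L]],
           "', column '", colnames(m)[bad[1L, 2L]], "' in ", file)
  }
  rownames(m) <- rn
  m
}

#' Write / read expression as TSV
#'
#' Each tissue assay is written as a lines x genes TSV (first column
#' `line_id`), plus one gene table (`gene_id`, `range_id`) shared by all
#' tissues. `readExpression` reassembles the
#' `SummarizedExperiment` (genes x lines).
#'
#' @param se expression `SummarizedExperiment` (genes x lines).
#' @param prefix output path prefix; files are
#'   `<prefix>_<tissue>.tsv` and `<prefix>_genes.tsv`.
#' @return `writeExpression`: invisibly, the written paths.
#' @export
writeExpression <- function(se, prefix) {
  paths <- character()
  genes <- data.frame(gene_id = rownames(se),
                      range_id = SummarizedExperiment::rowData(se)$range_id)
  gp <- paste0(prefix, "_genes.tsv")
  utils::write.table(genes, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- gp
  for (t in SummarizedExperiment::assayNames(se)) {
    m <- t(SummarizedExperiment::assay(se, t))
    df <- data.frame(line_id = rownames(m), m, check.names = FALSE)
    p <- paste0(prefix, "_", t, ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname writeExpression
#' @param files named character vector of per-tissue TSV paths (names =
#'   tissue tags).
#' @param genesFile path of the gene table TSV.
#' @return `readExpression`: a `SummarizedExperiment`.
#' @export
readExpression <- function(files, genesFile) {
  genes <- utils::read.delim(genesFile, stringsAsFactors = FALSE)
  assays <- lapply(files, function(f) t(readNumericTsv(f, "expression")))
  if (is.null(names(assays)))
    names(assays) <- sub("\\.tsv$", "", basename(files))
  for (a in assays)
    if (!identical(dimnames(a), dimnames(assays[[1L]])))
      stop("tissue files disagree on genes/lines")
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(gene_id = genes$gene_id,
                                   range_id = genes$range_id,
                                   row.names = genes$gene_id))
}

#' Write / read phenotypes as TSV
#'
#' Lines x traits table; first column `line_id`.
#'
#' @param pheno named numeric vector (one trait) or lines x traits matrix.
#' @param file TSV path.
#' @param traitName column name used when `pheno` is a vector.
#' @return `readPhenotype`: a lines x traits numeric matrix.
#' @export
writePhenotype <- function(pheno, file, traitName = "trait") {
  if (is.null(dim(pheno)))
    pheno <- matrix(pheno, ncol = 1L,
                    dimnames = list(names(pheno), traitName))
  df <- data.frame(line_id = rownames(pheno), pheno, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePhenotype
#' @export
readPhenotype <- function(file) {
  readNumericTsv(file, "phenotype")
}

#' Write / read a HareMatrix as TSV
#'
#' Long form: `gene_id`, `range_id`, `haplotype_id`, `effect`,
#' `provenance`, `mu`, `model`, `tissue`; one row per (gene, haplotype)
#' cell of the universe. Round trips are lossless.
#'
#' @param hare a [HareMatrix-class].
#' @param file TSV path.
#' @return `readHareMatrix`: a [HareMatrix-class].
#' @export
writeHareMatrix <- function(hare, file) {
  eff <- hare@effects
  idx <- which(!is.na(hare@provenance), arr.ind = TRUE)
  g <- rownames(eff)[idx[, 1L]]
  long <- data.frame(
    gene_id = g,
    range_id = if (length(hare@rangeIds)) unname(hare@rangeIds[g]) else NA,
    haplotype_id = colnames(eff)[idx[, 2L]],
    effect = eff[idx],
    provenance = hare@provenance[idx],
    mu = unname(hare@mu[g]),
    model = hare@model,
    tissue = hare@tissue)
  long <- long[order(long$gene_id, as.integer(long$haplotype_id)), ]
  utils::write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeHareMatrix
#' @export
readHareMatrix <- function(file) {
  long <- utils::read.delim(file, stringsAsFactors = FALSE,
                            colClasses = c(haplotype_id = "character"))
  genes <- unique(long$gene_id)
  universe <- unique(long$haplotype_id)
  universe <- universe[order(suppressWarnings(as.numeric(universe)),
                             universe)]
  eff <- matrix(NA_real_, length(genes), length(universe),
                dimnames = list(genes, universe))
  prov <- matrix(NA_character_, length(genes), length(universe),
                 dimnames = list(genes, universe))
  ij <- cbind(match(long$gene_id, genes), match(long$haplotype_id, universe))
  eff[ij] <- long$effect
  prov[ij] <- long$provenance
  mu <- stats::setNames(long$mu[!duplicated(long$gene_id)], genes)
  rng <- stats::setNames(as.character(long$range_id[!duplicated(long$gene_id)]),
                         genes)
  new("HareMatrix", effects = eff, mu = mu, provenance = prov,
      model = as.integer(long$model[1L]),
      tissue = as.character(long$tissue[1L]), rangeIds = rng)
}

#' Read a SNP dosage matrix (VCF or TSV)
#'
#' VCF (via the vcfR package): genotypes are converted to ALT-allele
#' dosages; heterozygous calls in inbred material are accepted as dosage 1
#' with a warning. TSV: one row per site with columns `chrom`, `pos`
#' (1-based, like VCF), `ref`, `alt`, then one 0/1/2 column per line.
#' Positions are converted to 0-based internally and must be strictly
#' increasing within a chromosome.
#'
#' @param file path to a `.vcf`/`.vcf.gz` or TSV file.
#' @return a list of class `"SnpMatrix"`: `dosage` (lines x sites integer
#'   matrix) and `sites` (data.frame `chrom`, `pos` (0-based), `ref`,
#'   `alt`).
#' @export
readSnpMatrix <- function(file) {
  if (grepl("\\.vcf(\\.gz)?$", file)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("vcfR is required to read VCF")
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    gt <- gsub("|", "/", vcfR::extract.gt(v, element = "GT"), fixed = TRUE)
    conv <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    dos <- matrix(conv[gt], nrow(gt), ncol(gt), dimnames = dimnames(gt))
    dos <- t(dos)  # lines x sites
    sites <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
                        pos = as.integer(v@fix[, "POS"]) - 1L,
                        ref = as.character(v@fix[, "REF"]),
                        alt = as.character(v@fix[, "ALT"]))
  } else {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(df)))
      stop("SNP TSV must have columns ", paste(need, collapse = ", "))
    sites <- data.frame(chrom = as.character(df$chrom),
                        pos = as.integer(df$pos) - 1L,
                        ref = df$ref, alt = df$alt)
    dos <- t(as.matrix(df[, setdiff(names(df), need), drop = FALSE]))
    storage.mode(dos) <- "integer"
  }
  colnames(dos) <- sprintf("%s_%d", sites$chrom, sites$pos + 1L)
  if (!all(dos %in% c(0L, 1L, 2L) | is.na(dos)))
    stop("dosages must be 0, 1 or 2")
  if (any(dos == 1L, na.rm = TRUE))
    warning(sum(dos == 1L, na.rm = TRUE),
            " heterozygous call(s) in inbred material (dosage 1 accepted)")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  if (any(unlist(tapply(sites$pos, sites$chrom, function(p) diff(p) <= 0))))
    stop("positions must be strictly increasing within a chromosome")
  structure(list(dosage = dos, sites = sites), class = "SnpMatrix")
}

#' Minor-allele-frequency filter
#'
#' Keeps sites whose minor allele frequency is strictly greater than
#' `minMaf` (equivalently major allele frequency strictly below
#' `1 - minMaf`); a site at exactly the threshold is removed.
#'
#' @param snps a `"SnpMatrix"` from [readSnpMatrix()].
#' @param minMaf threshold (default 0.05).
#' @return a filtered `"SnpMatrix"`.
#' @export
mafFilter <- function(snps, minMaf = 0.05) {
  if (!ncol(snps$dosage)) stop("empty SNP matrix")
  p <- colMeans(snps$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > minMaf
  if (!any(keep)) warning("no site passes the MAF filter")
  structure(list(dosage = snps$dosage[, keep, drop = FALSE],
                 sites = snps$sites[keep, , drop = FALSE]),
            class = "SnpMatrix")
}

#' Window-based LD pruning
#'
#' Greedy left-to-right scan per chromosome: a site is dropped if its
#' squared Pearson correlation with any already retained site within
#' `windowBp` upstream exceeds `r2Max`. The scan order (genome position)
#' makes the result deterministic; it is invariant to flipping any site's
#' allele coding (r^2 is unchanged).
#'
#' @param snps a `"SnpMatrix"` (MAF-filtered).
#' @param r2Max squared-correlation threshold (default 0.9, strict).
#' @param windowBp window size in base pairs (default 100000).
#' @return a pruned `"SnpMatrix"`.
#' @export
ldPrune <- function(snps, r2Max = 0.9, windowBp = 1e5) {
  sites <- snps$sites
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    kept <- integer()
    for (i in idx) {
      inWin <- kept[sites$pos[kept] >= sites$pos[i] - windowBp]
      drop <- FALSE
      if (length(inWin)) {
        r <- suppressWarnings(stats::cor(snps$dosage[, i],
                                         snps$dosage[, inWin, drop = FALSE],
                                         use = "pairwise.complete.obs"))
        drop <- any(r^2 > r2Max, na.rm = TRUE)
      }
      if (!drop) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  structure(list(dosage = snps$dosage[, keep, drop = FALSE],
                 sites = snps$sites[keep, , drop = FALSE]),
            class = "SnpMatrix")
}
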