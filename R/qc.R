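#' @importFrom stats quantile sd loess predict
#' @importFrom utils head
NULL

#' QC thresholds for cell filtering
#'
#' Per-sample bounds on RNA/ATAC totals, detected genes and (when the
#' metadata carries them) TSS enrichment and mitochondrial fraction. Any
#' bound may be the string `"auto"`, resolved per sample as the 1st/99th
#' percentile of the metric (minimum and maximum outlier removal), or
#' `NULL` to disable.
#'
#' @param minRnaCounts,maxRnaCounts bounds on per-cell RNA totals
#' @param minAtacCounts,maxAtacCounts bounds on per-cell ATAC totals
#' @param minGenes,maxGenes bounds on detected genes per cell
#' @param minTssEnrichment lower bound on the `tss_enrichment` column
#' @param maxMitoFraction upper bound on the `mito_fraction` column
#' @return a `QcThresholds` list.
#' @export
qcThresholds <- function(minRnaCounts = NULL, maxRnaCounts = NULL,
                         minAtacCounts = NULL, maxAtacCounts = NULL,
                         minGenes = NULL, maxGenes = NULL,
                         minTssEnrichment = NULL, maxMitoFraction = NULL) {
  th <- list(minRnaCounts = minRnaCounts, maxRnaCounts = maxRnaCounts,
             minAtacCounts = minAtacCounts, maxAtacCounts = maxAtacCounts,
             minGenes = minGenes, maxGenes = maxGenes,
             minTssEnrichment = minTssEnrichment,
             maxMitoFraction = maxMitoFraction)
  num <- function(x) is.numeric(x) && length(x) == 1
  chk <- function(lo, hi, what) {
    if (num(th[[lo]]) && num(th[[hi]]) && th[[lo]] > th[[hi]])
      stop(sprintf("%s: min > max", what))
  }
  chk("minRnaCounts", "maxRnaCounts", "RNA counts")
  chk("minAtacCounts", "maxAtacCounts", "ATAC counts")
  chk("minGenes", "maxGenes", "detected genes")
  class(th) <- "QcThresholds"
  th
}

.resolveBound <- function(bound, values, side) {
  if (is.null(bound)) return(if (side == "min") -Inf else Inf)
  if (identical(bound, "auto"))
    return(unname(quantile(values, if (side == "min") 0.01 else 0.99)))
  bound
}

#' Filter low-quality cells
#'
#' Removes, per sample, cells outside the resolved minimum/maximum bounds
#' on RNA totals, ATAC totals, detected genes and optional metadata
#' metrics. `"auto"` bounds are the per-sample 1st/99th percentiles.
#' Idempotent on fixed numeric thresholds.
#'
#' @param dataset a [MultiomeExperiment-class]
#' @param thresholds a [qcThresholds()] object
#' @return list with `dataset` (filtered) and `report` (one row per
#'   sample: cells before/after, removed, and the resolved numeric bounds).
#'   Samples losing all their cells are dropped with a warning.
#' @export
filterCells <- function(dataset, thresholds = qcThresholds()) {
  stopifnot(inherits(thresholds, "QcThresholds"))
  cd <- cellData(dataset)
  rnaTot <- Matrix::colSums(rnaCounts(dataset))
  atacTot <- Matrix::colSums(atacCounts(dataset))
  nGene <- Matrix::colSums(rnaCounts(dataset) > 0)
  samples <- as.character(cd$sample)
  keep <- rep(TRUE, nrow(cd))
  report <- NULL
  for (s in unique(samples)) {
    idx <- which(samples == s)
    lo1 <- .resolveBound(thresholds$minRnaCounts, rnaTot[idx], "min")
    hi1 <- .resolveBound(thresholds$maxRnaCounts, rnaTot[idx], "max")
    lo2 <- .resolveBound(thresholds$minAtacCounts, atacTot[idx], "min")
    hi2 <- .resolveBound(thresholds$maxAtacCounts, atacTot[idx], "max")
    lo3 <- .resolveBound(thresholds$minGenes, nGene[idx], "min")
    hi3 <- .resolveBound(thresholds$maxGenes, nGene[idx], "max")
    ok <- rnaTot[idx] >= lo1 & rnaTot[idx] <= hi1 &
          atacTot[idx] >= lo2 & atacTot[idx] <= hi2 &
          nGene[idx] >= lo3 & nGene[idx] <= hi3
    if (!is.null(thresholds$minTssEnrichment) && !is.null(cd$tss_enrichment)) {
      lo <- .resolveBound(thresholds$minTssEnrichment, cd$tss_enrichment[idx], "min")
      ok <- ok & cd$tss_enrichment[idx] >= lo
    }
    if (!is.null(thresholds$maxMitoFraction) && !is.null(cd$mito_fraction)) {
      hi <- .resolveBound(thresholds$maxMitoFraction, cd$mito_fraction[idx], "max")
      ok <- ok & cd$mito_fraction[idx] <= hi
    }
    keep[idx] <- ok
    report <- rbind(report, data.frame(
      sample = s, n_before = length(idx), n_after = sum(ok),
      n_removed = sum(!ok),
      min_rna = lo1, max_rna = hi1, min_atac = lo2, max_atac = hi2,
      min_genes = lo3, max_genes = hi3))
    if (!any(ok)) warning("all cells removed for sample ", s,
                          "; sample dropped")
  }
  list(dataset = dataset[keep], report = report)
}

#' Fraction of reads in peaks (FRiP) per cell
#'
#' In-peak fragments divided by total fragments per cell. Total fragments
#' come from the `total_fragments` metadata column when present (in-peak
#' plus off-peak), otherwise from the in-peak sum alone.
#'
#' @param dataset a [MultiomeExperiment-class]
#' @return list with `frip` (named per-cell vector; `NA` and a flag for
#'   zero-fragment cells), `flagged` (barcodes with undefined FRiP) and
#'   `sampleMeans`.
#' @export
fripScore <- function(dataset) {
  inPeak <- Matrix::colSums(atacCounts(dataset))
  cd <- cellData(dataset)
  total <- if (!is.null(cd$total_fragments)) as.numeric(cd$total_fragments) else inPeak
  frip <- ifelse(total > 0, inPeak / total, NA_real_)
  names(frip) <- rownames(cd)
  flagged <- names(frip)[is.na(frip)]
  sm <- tapply(frip, as.character(cd$sample), mean, na.rm = TRUE)
  list(frip = frip, flagged = flagged, sampleMeans = sm)
}

.tagNormalized <- function(m, method, scaleFactor) {
  attr(m, "method") <- method
  attr(m, "scaleFactor") <- scaleFactor
  m
}

#' Library-size log-normalization
#'
#' Each count is divided by its cell's total, multiplied by `scaleFactor`
#' and natural-log transformed as `ln(1 + count / total * scaleFactor)`.
#' Zeros are preserved; the sparsity pattern is unchanged.
#'
#' @param counts features x cells count matrix (sparse or dense)
#' @param scaleFactor scale factor (default 10,000)
#' @return normalized sparse matrix tagged with `method = "lognorm"`.
#' @export
logNormalize <- function(counts, scaleFactor = 1e4) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dgCMatrix")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stop("zero-count cells: ",
         paste(head(colnames(counts)[cs == 0], 5), collapse = ", "))
  out <- counts
  ## operate on the sparse slots directly: x entries belong to column j+1
  j <- rep(seq_len(ncol(counts)), diff(counts@p))
  out@x <- log1p(counts@x / cs[j] * scaleFactor)
  .tagNormalized(out, "lognorm", scaleFactor)
}

#' TF-IDF normalization for peak counts
#'
#' Term frequency is the count divided by the cell total; inverse document
#' frequency is the number of cells over the number of cells in which the
#' peak is detected. Values are `ln(1 + TF * IDF * scaleFactor)`; zeros
#' are preserved.
#'
#' @param counts peaks x cells count matrix
#' @param scaleFactor scale factor (default 10,000)
#' @return normalized sparse matrix tagged with `method = "tfidf"`.
#' @export
tfidfNormalize <- function(counts, scaleFactor = 1e4) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dgCMatrix")
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stop("zero-count cells: ",
         paste(head(colnames(counts)[cs == 0], 5), collapse = ", "))
  ncellsWith <- Matrix::rowSums(counts > 0)
  if (any(ncellsWith == 0))
    stop("all-zero peaks: ",
         paste(head(rownames(counts)[ncellsWith == 0], 5), collapse = ", "))
  idf <- ncol(counts) / ncellsWith
  out <- counts
  j <- rep(seq_len(ncol(counts)), diff(counts@p))
  i <- counts@i + 1L
  out@x <- log1p(counts@x / cs[j] * idf[i] * scaleFactor)
  .tagNormalized(out, "tfidf", scaleFactor)
}

#' Gene activity from peak counts
#'
#' Sums, per gene and cell, the counts of peaks overlapping the gene body
#' extended 500 bp upstream of the TSS (strand-aware), then log-normalizes
#' the resulting genes x cells matrix with scale factor 10,000.
#'
#' @param dataset a [MultiomeExperiment-class]
#' @param upstream promoter extension upstream of the TSS in bp
#' @param scaleFactor scale factor for the log-normalization
#' @param normalize set FALSE to return raw summed counts
#' @return genes x cells activity matrix (`method = "geneactivity-lognorm"`).
#' @export
geneActivity <- function(dataset, upstream = 500, scaleFactor = 1e4,
                         normalize = TRUE) {
  genes <- geneRanges(dataset)
  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*")) stop("genes missing strand: ",
                            paste(head(names(genes)[str == "*"], 5), collapse = ", "))
  ext <- genes
  plus <- str == "+"
  GenomicRanges::start(ext)[plus] <-
    pmax(1L, GenomicRanges::start(ext)[plus] - as.integer(upstream))
  GenomicRanges::end(ext)[!plus] <-
    GenomicRanges::end(ext)[!plus] + as.integer(upstream)
  hits <- GenomicRanges::findOverlaps(ext, peakRanges(dataset))
  ind <- Matrix::sparseMatrix(
    i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits),
    x = 1, dims = c(length(genes), length(peakRanges(dataset))))
  act <- ind %*% atacCounts(dataset)
  dimnames(act) <- list(names(genes), colnames(atacCounts(dataset)))
  act <- methods::as(methods::as(act, "CsparseMatrix"), "dgCMatrix")
  if (!normalize) return(.tagNormalized(act, "geneactivity-counts", NA))
  cs <- Matrix::colSums(act)
  keepCells <- cs > 0
  out <- act
  j <- rep(seq_len(ncol(act)), diff(act@p))
  denom <- ifelse(cs == 0, 1, cs)
  out@x <- log1p(act@x / denom[j] * scaleFactor)
  .tagNormalized(out, "geneactivity-lognorm", scaleFactor)
}

#' Variable-feature selection
#'
#' Genes are ranked by variance-stabilized standardized variance: a loess
#' trend of log10 variance on log10 mean predicts each gene's expected
#' s.d.; counts are standardized by mean and predicted s.d. (clipped at
#' `sqrt(n)`) and the variance of the standardized values ranks the genes.
#' Peaks are selected by commonness: all peaks detected in at least the
#' `1 - peakQuantile` fraction quantile of per-peak cell counts, i.e. the
#' most common `peakQuantile` share of peaks.
#'
#' @param rnaCounts genes x cells raw counts
#' @param n number of variable genes (default 2,000)
#' @param atacCounts optional peaks x cells raw counts
#' @param peakQuantile fraction of most common peaks to keep (default 0.95)
#' @param loessSpan span of the mean-variance trend
#' @return list with `genes` (character, length `min(n, nGenes)` ranked by
#'   standardized variance), `geneVariance` (full table) and `peaks`.
#' @export
selectVariableFeatures <- function(rnaCounts, n = 2000,
                                   atacCounts = NULL, peakQuantile = 0.95,
                                   loessSpan = 0.3) {
  m <- methods::as(methods::as(rnaCounts, "CsparseMatrix"), "dgCMatrix")
  if (n > nrow(m)) stop("n exceeds the number of genes")
  mu <- Matrix::rowMeans(m)
  v <- rowVarsSparse(m)
  standVar <- rep(0, nrow(m))
  use <- v > 0 & mu > 0
  if (sum(use) >= 10) {
    fit <- loess(log10(v[use]) ~ log10(mu[use]), span = loessSpan, degree = 2)
    expSd <- sqrt(10^predict(fit))
    clip <- sqrt(ncol(m))
    mm <- m[use, , drop = FALSE]
    ## variance of clipped standardized counts, computed sparsely:
    ## z = (x - mu)/sd, zeros give -mu/sd per cell
    nC <- ncol(m)
    muU <- mu[use]
    zsum <- numeric(sum(use)); zsq <- numeric(sum(use))
    jj <- rep(seq_len(nC), diff(mm@p))
    ii <- mm@i + 1L
    z <- pmin((mm@x - muU[ii]) / expSd[ii], clip)
    z0 <- pmax(pmin(-muU / expSd, clip), -clip)  # value at zero counts
    nz <- tabulate(ii, nbins = sum(use))
    zsum <- tapply2(z, ii, sum, sum(use)) + (nC - nz) * z0
    zsq <- tapply2(z^2, ii, sum, sum(use)) + (nC - nz) * z0^2
    standVar[use] <- (zsq - zsum^2 / nC) / (nC - 1)
  } else {
    standVar <- v
  }
  ord <- order(standVar, decreasing = TRUE)
  tab <- data.frame(gene = rownames(m), mean = mu, variance = v,
                    standardizedVariance = standVar)
  res <- list(genes = rownames(m)[ord][seq_len(n)], geneVariance = tab)
  if (!is.null(atacCounts)) {
    a <- methods::as(methods::as(atacCounts, "CsparseMatrix"), "dgCMatrix")
    det <- Matrix::rowSums(a > 0)
    floorQ <- quantile(det, 1 - peakQuantile)
    res$peaks <- rownames(a)[det >= floorQ]
  }
  res
}

## row variances of a sparse matrix without densifying
rowVarsSparse <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  sq <- Matrix::rowSums(m^2)
  (sq - n * mu^2) / (n - 1)
}

## grouped sum with guaranteed length (tapply drops empty groups)
tapply2 <- function(x, idx, f, nbins) {
  out <- numeric(nbins)
  s <- tapply(x, idx, f)
  out[as.integer(names(s))] <- s
  out
}

#' Row standardization
#'
#' Centers each row and scales it by its sample (n-1) standard deviation,
#' clipping to `[-clip, clip]`; constant rows become 0. Idempotent up to
#' clipping.
#'
#' @param x features x cells matrix
#' @param clip symmetric clip value (default 10)
#' @return dense standardized matrix tagged `method = "standardized"`.
#' @export
standardizeRows <- function(x, clip = 10) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  out <- (x - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out <- pmin(pmax(out, -clip), clip)
  .tagNormalized(out, "standardized", NA)
}
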