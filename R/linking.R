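#' @importFrom stats cor pt p.adjust
NULL

## peak centers on the 1-based stored coordinates
.peakCenter <- function(peaks) {
  floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
}

#' Correlation-based peak-gene linking
#'
#' For every (peak, gene) pair with the peak center within `maxDist` bp of
#' the gene's strand-aware TSS (same chromosome) and the peak detected in
#' at least `minCells` cells, the Pearson correlation between normalized
#' expression and normalized accessibility across cells is computed with a
#' two-sided t-test (df = n - 2). Pairs with a positive r and p below
#' `pMax` (and, when `padjMax` is given, BH-adjusted p below it) are
#' retained. Constant peak or gene vectors are skipped and logged.
#'
#' @param expr genes x cells normalized expression
#' @param access peaks x cells normalized accessibility
#' @param peaks `GRanges` of the access rows
#' @param genes `GRanges` with `tss` metadata for the expr rows
#' @param maxDist TSS-to-peak-center distance cap in bp (default 50,000)
#' @param minCells minimum cells in which a peak is detected (default 10)
#' @param pMax raw p-value cutoff (default 0.05)
#' @param padjMax optional BH-adjusted p cutoff (applied on top of `pMax`)
#' @param windowTag window label recorded on the links
#' @return data.frame of retained links (`peak`, `gene`, `r`, `p`, `padj`,
#'   `distance`, `window`), BH adjustment computed across all tested
#'   pairs; skipped constant pairs are in `attr(, "skipped")`.
#' @export
linkPeaks <- function(expr, access, peaks, genes, maxDist = 50000,
                      minCells = 10, pMax = 0.05, padjMax = NULL,
                      windowTag = paste0(round(maxDist / 1000), "kb")) {
  stopifnot(identical(colnames(expr), colnames(access)))
  n <- ncol(expr)
  peaks <- peaks[rownames(access)]
  genes <- genes[rownames(expr)]
  detected <- Matrix::rowSums(access != 0)
  pc <- .peakCenter(peaks)
  pchr <- as.character(GenomicRanges::seqnames(peaks))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  exprD <- as.matrix(expr)
  accD <- as.matrix(access)

  rows <- vector("list", length(genes))
  skipped <- character()
  for (gi in seq_along(genes)) {
    cand <- which(pchr == gchr[gi] & abs(pc - genes$tss[gi]) <= maxDist &
                  detected >= minCells)
    if (!length(cand)) next
    x <- exprD[gi, ]
    if (sd(x) == 0) {
      skipped <- c(skipped, paste0(names(genes)[gi], ":constant-gene"))
      next
    }
    A <- accD[cand, , drop = FALSE]
    sds <- apply(A, 1, sd)
    if (any(sds == 0)) {
      skipped <- c(skipped, paste0(names(genes)[gi], ":",
                                   rownames(A)[sds == 0], ":constant-peak"))
      cand <- cand[sds > 0]
      A <- A[sds > 0, , drop = FALSE]
      if (!length(cand)) next
    }
    r <- as.numeric(cor(x, t(A)))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    rows[[gi]] <- data.frame(peak = names(peaks)[cand],
                             gene = names(genes)[gi],
                             r = r, p = p,
                             distance = pc[cand] - genes$tss[gi],
                             stringsAsFactors = FALSE)
  }
  tested <- do.call(rbind, rows)
  if (is.null(tested))
    tested <- data.frame(peak = character(), gene = character(),
                         r = numeric(), p = numeric(), distance = numeric())
  tested$padj <- p.adjust(tested$p, method = "BH")
  keep <- tested$r > 0 & tested$p < pMax
  if (!is.null(padjMax)) keep <- keep & tested$padj < padjMax
  out <- tested[keep, c("peak", "gene", "r", "p", "padj", "distance")]
  rownames(out) <- NULL
  out$window <- rep(windowTag, nrow(out))
  attr(out, "skipped") <- skipped
  attr(out, "nTested") <- nrow(tested)
  out
}

#' Per-cell enhancer score
#'
#' For each gene, the fragments in its linked peaks divided by the cell's
#' total fragments in all peaks, times `scaleFactor`. Cells with no
#' in-peak fragments get `NA` and are flagged.
#'
#' @param atacCounts peaks x cells raw counts (all peaks, for the
#'   denominator)
#' @param links data.frame from [linkPeaks()]
#' @param scaleFactor default 10,000
#' @return genes x cells score matrix; flagged barcodes in
#'   `attr(, "flagged")`.
#' @export
enhancerScore <- function(atacCounts, links, scaleFactor = 1e4) {
  total <- Matrix::colSums(atacCounts)
  genesU <- unique(links$gene)
  out <- matrix(0, nrow = length(genesU), ncol = ncol(atacCounts),
                dimnames = list(genesU, colnames(atacCounts)))
  for (g in genesU) {
    pks <- links$peak[links$gene == g]
    out[g, ] <- Matrix::colSums(atacCounts[pks, , drop = FALSE])
  }
  denom <- ifelse(total > 0, total, NA_real_)
  out <- sweep(out, 2, denom, "/") * scaleFactor
  attr(out, "flagged") <- colnames(atacCounts)[total == 0]
  out
}

#' Define DORCs and compute DORC scores
#'
#' Genes connected to at least `minLinks` peaks within the 50-kb window
#' are flagged as DORCs (domains of regulatory chromatin) and re-linked on
#' the expanded window (default 500 kb) under the same positive-r,
#' p < `pMax` rule; the per-cell DORC score is the [enhancerScore()] over
#' the expanded link sets.
#'
#' @param links links from [linkPeaks()] at the base (50 kb) window
#' @param expr,access,peaks,genes as in [linkPeaks()]
#' @param atacCounts raw peak counts for scoring
#' @param minLinks minimum 50-kb links for DORC status (default 5)
#' @param expandedDist expanded window (default 500,000)
#' @param minCells,pMax,padjMax passed to the expanded [linkPeaks()] run
#' @param unionLinks when TRUE score over the union of base and expanded
#'   link sets (default: expanded set, which nests the base set under the
#'   raw-p rule)
#' @return list with `genes` (gene, nLinks at 50 kb, dorc flag),
#'   `links` (expanded links of DORC genes) and `scores` (DORC genes x
#'   cells). Empty with a warning when no gene qualifies.
#' @export
defineDorcs <- function(links, expr, access, peaks, genes, atacCounts,
                        minLinks = 5, expandedDist = 500000,
                        minCells = 10, pMax = 0.05, padjMax = NULL,
                        unionLinks = FALSE) {
  nLinks <- table(links$gene)
  tab <- data.frame(gene = names(nLinks), nLinks50 = as.integer(nLinks),
                    dorc = as.integer(nLinks) >= minLinks,
                    stringsAsFactors = FALSE)
  dorcGenes <- tab$gene[tab$dorc]
  if (!length(dorcGenes)) {
    warning("no genes with >= ", minLinks, " linked peaks")
    return(list(genes = tab, links = links[0, ],
                scores = matrix(0, 0, ncol(atacCounts))))
  }
  expanded <- linkPeaks(expr[dorcGenes, , drop = FALSE], access,
                        peaks, genes[dorcGenes],
                        maxDist = expandedDist, minCells = minCells,
                        pMax = pMax, padjMax = padjMax,
                        windowTag = paste0(round(expandedDist / 1000), "kb"))
  if (unionLinks) {
    base <- links[links$gene %in% dorcGenes, ]
    expanded <- unique(rbind(expanded, base[, colnames(expanded)]))
  }
  scores <- enhancerScore(atacCounts, expanded)
  list(genes = tab, links = expanded, scores = scores)
}

#' Binned genome track from grouped ATAC counts
#'
#' Tiles the covered chromosomes into fixed-width bins, assigns each
#' peak's group-aggregated count to every bin it overlaps, and normalizes
#' by the group's sequencing depth: the `bigwig` variant multiplies by
#' `scaleFactor` and divides by the group's total in-peak fragments; the
#' `track` variant divides by (number of cells x mean depth per cell),
#' i.e. the group total, without the scale factor. Either way, groups of
#' equal per-cell signal but different sizes produce equal values.
#'
#' @param atacCounts peaks x cells raw counts
#' @param peaks `GRanges` for the rows
#' @param group barcodes (or index) of the cell group
#' @param bin bin width in bp (default 100)
#' @param variant `"bigwig"` or `"track"`
#' @param scaleFactor for the bigwig variant (default 10,000)
#' @return bedGraph-style data.frame (`chrom`, `start` 0-based, `end`,
#'   `value`), nonzero bins only.
#' @export
binnedTrack <- function(atacCounts, peaks, group, bin = 100,
                        variant = c("bigwig", "track"), scaleFactor = 1e4) {
  variant <- match.arg(variant)
  if (!length(group)) stop("empty cell group")
  sub <- atacCounts[, group, drop = FALSE]
  peakSum <- Matrix::rowSums(sub)
  total <- sum(peakSum)
  if (total == 0) stop("group has no in-peak fragments")
  norm <- if (variant == "bigwig") scaleFactor / total else 1 / total
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1L  # 0-based half-open
  end0 <- GenomicRanges::end(peaks)
  out <- NULL
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch & peakSum > 0)
    if (!length(idx)) next
    firstBin <- start0[idx] %/% bin
    lastBin <- (end0[idx] - 1L) %/% bin
    reps <- lastBin - firstBin + 1L
    binIdx <- unlist(mapply(seq, firstBin, lastBin, SIMPLIFY = FALSE))
    vals <- rep(peakSum[idx], reps)
    agg <- tapply(vals, binIdx, sum)
    b <- as.integer(names(agg))
    out <- rbind(out, data.frame(chrom = ch, start = b * bin,
                                 end = (b + 1L) * bin,
                                 value = as.numeric(agg) * norm))
  }
  out[order(out$chrom, out$start), ]
}
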