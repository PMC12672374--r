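#' @importFrom GenomicRanges reduce findOverlaps countOverlaps
#'   distanceToNearest
NULL

## recenter ranges to a fixed even width: a range with floor-midpoint c
## becomes [c - width/2, c + width/2) in 0-based half-open coordinates
## (stored 1-based as [c - width/2 + 1, c + width/2])
.recenter <- function(gr, width) {
  center <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2
  out <- GRanges(GenomicRanges::seqnames(gr),
                 IRanges(center - width %/% 2 + 1, center + width %/% 2),
                 strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

#' Build nonoverlapping 1-kb TSS windows
#'
#' Each TSS is extended 25 bp up- and downstream; overlapping extensions
#' are merged strand-aware; merged regions are recentered and resized to
#' 1 kb; a final strand-blind merge removes any overlap the resizing
#' recreated (merged composites may exceed 1 kb, preserving nonoverlap).
#' Every window is annotated with the closest gene (TSS distance, ties
#' broken by the lexicographically smallest gene id).
#'
#' @param tss `GRanges` of transcript TSS positions (width-1 ranges or
#'   ranges whose strand-aware start is the TSS) with a `gene` metadata
#'   column and definite strand
#' @param flank initial extension around the TSS (default 25)
#' @param width final window width (default 1,000)
#' @return `GRanges` of pairwise nonoverlapping windows with metadata
#'   `gene` (closest) and `n_tss` (TSSs merged into the window).
#' @export
buildTssWindows <- function(tss, flank = 25, width = 1000) {
  str <- as.character(GenomicRanges::strand(tss))
  if (any(str == "*")) stop("TSS entries missing strand")
  if (is.null(tss$gene)) stop("tss must carry a 'gene' metadata column")
  pos <- ifelse(str == "-", GenomicRanges::end(tss),
                GenomicRanges::start(tss))
  pt <- GRanges(GenomicRanges::seqnames(tss),
                IRanges(pos - flank, pos + flank), strand = str)
  pt$gene <- tss$gene
  merged <- reduce(pt, with.revmap = TRUE)           # strand-aware
  sized <- .recenter(merged, width)
  final <- reduce(sized, ignore.strand = TRUE, with.revmap = TRUE)
  nTss <- vapply(final$revmap, function(ix)
    sum(lengths(merged$revmap[ix])), integer(1))
  ## closest-gene consensus per window
  tssPoint <- GRanges(GenomicRanges::seqnames(tss), IRanges(pos, pos))
  genes <- as.character(tss$gene)
  hit <- distanceToNearest(final, tssPoint, select = "all",
                           ignore.strand = TRUE)
  dmin <- tapply(S4Vectors::mcols(hit)$distance,
                 S4Vectors::queryHits(hit), min)
  gene <- character(length(final))
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  dd <- S4Vectors::mcols(hit)$distance
  for (i in seq_along(final)) {
    cand <- genes[sh[qh == i & dd == dmin[as.character(i)]]]
    gene[i] <- sort(cand)[1]
  }
  final$gene <- gene
  final$n_tss <- nTss
  final$revmap <- NULL
  final
}

#' Build nonoverlapping 1-kb enhancer regions from cCREs
#'
#' Candidate cis-regulatory elements overlapping any TSS window (by >= 1
#' bp) are removed; survivors are merged, recentered and resized to 1 kb,
#' re-merged to restore nonoverlap, and regions without consensus-peak
#' support are discarded. Genes are assigned through a supplied
#' peak-to-gene interaction table when given.
#'
#' @param ccres `GRanges` of enhancer cCRE intervals
#' @param tssWindows `GRanges` from [buildTssWindows()]
#' @param consensusPeaks `GRanges` of consensus peaks; regions not
#'   overlapping any are dropped
#' @param peakToGene optional data.frame (`peak`, `gene`) plus a `peaks`
#'   `GRanges` named by peak id, used to annotate regions by overlap
#' @param peaks optional `GRanges` backing `peakToGene$peak`
#' @param width final region width (default 1,000)
#' @return `GRanges` of nonoverlapping enhancer regions (metadata `genes`:
#'   comma-collapsed assigned genes, may be empty). Empty input yields an
#'   empty set with a warning.
#' @export
buildEnhancerRegions <- function(ccres, tssWindows, consensusPeaks,
                                 peakToGene = NULL, peaks = NULL,
                                 width = 1000) {
  if (!length(ccres)) {
    warning("empty cCRE input")
    return(GRanges())
  }
  ov <- findOverlaps(ccres, tssWindows, ignore.strand = TRUE)
  keep <- ccres[setdiff(seq_along(ccres), unique(S4Vectors::queryHits(ov)))]
  if (!length(keep)) {
    warning("no cCREs survive TSS-window filtering")
    return(GRanges())
  }
  merged <- reduce(keep)
  sized <- .recenter(merged, width)
  final <- reduce(sized, ignore.strand = TRUE)
  supported <- countOverlaps(final, consensusPeaks, ignore.strand = TRUE) > 0
  final <- final[supported]
  genesCol <- rep("", length(final))
  if (!is.null(peakToGene) && !is.null(peaks) && length(final)) {
    ov2 <- findOverlaps(final, peaks[peakToGene$peak], ignore.strand = TRUE)
    if (length(ov2)) {
      byRegion <- split(peakToGene$gene[S4Vectors::subjectHits(ov2)],
                        S4Vectors::queryHits(ov2))
      for (nm in names(byRegion))
        genesCol[as.integer(nm)] <- paste(sort(unique(byRegion[[nm]])),
                                          collapse = ",")
    }
  }
  final$genes <- genesCol
  final
}

#' Count fragments per region
#'
#' Any-overlap (>= 1 bp) counting of fragments in each region, one count
#' column per sample; a fragment spanning two regions counts in both.
#'
#' @param fragments a named list of `GRanges` (one per sample) or a
#'   single `GRanges`
#' @param regions `GRanges` of regions (e.g. a window set)
#' @return integer matrix regions x samples.
#' @export
countRegions <- function(fragments, regions) {
  if (methods::is(fragments, "GRanges")) fragments <- list(sample1 = fragments)
  out <- vapply(fragments, function(fr)
    countOverlaps(regions, fr, ignore.strand = TRUE),
    integer(length(regions)))
  out <- matrix(as.integer(out), nrow = length(regions),
                dimnames = list(names(regions), names(fragments)))
  out
}

#' TMM-normalized negative-binomial likelihood-ratio testing
#'
#' edgeR pipeline for bulk count tables: TMM normalization factors,
#' common + trended + tagwise dispersion estimation, NB GLM fit under
#' `~ replicate + condition` (replicate dropped when constant) and a
#' likelihood-ratio test for the requested contrast, with BH FDR control.
#' All-zero features are removed before fitting.
#'
#' @param counts features x samples integer matrix
#' @param condition per-sample condition factor
#' @param replicate optional per-sample replicate (batch) factor
#' @param contrast length-2 character `c(numerator, denominator)` of
#'   condition levels
#' @return data.frame with `feature`, `logFC` (log2), `logCPM`, `p`,
#'   `fdr`; TMM factors in `attr(, "normFactors")`.
#' @export
tmmNbLrt <- function(counts, condition, replicate = NULL, contrast) {
  condition <- factor(condition)
  if (any(table(condition) < 2))
    stop("at least 2 replicates per condition required")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  useRep <- !is.null(replicate) && length(unique(replicate)) > 1
  design <- if (useRep)
    stats::model.matrix(~0 + condition + factor(replicate))
  else stats::model.matrix(~0 + condition)
  colnames(design) <- sub("^condition", "", colnames(design))
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  cvec <- rep(0, ncol(design))
  stopifnot(all(contrast %in% colnames(design)))
  cvec[match(contrast[1], colnames(design))] <- 1
  cvec[match(contrast[2], colnames(design))] <- -1
  lrt <- edgeR::glmLRT(fit, contrast = cvec)
  tab <- edgeR::topTags(lrt, n = Inf, sort.by = "none")$table
  out <- data.frame(feature = rownames(tab), logFC = tab$logFC,
                    logCPM = tab$logCPM, p = tab$PValue, fdr = tab$FDR,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "normFactors") <- dge$samples$norm.factors
  out
}

#' Gate epigenetic-memory genes
#'
#' A gene is called a memory gene when it is upregulated on the first
#' stimulus at the RNA level (p < `rnaP` and FDR < `rnaFdr`, positive
#' logFC) AND its chromatin accessibility is unchanged between the first
#' stimulus and the washout (|logFC| < `atacLfc` and FDR > `atacFdr`).
#' Genes additionally significantly upregulated on the second stimulus
#' versus the first (p and FDR below the RNA thresholds) form the
#' asterisk class; those reaching p < `rnaP` only form the weak class
#' (asterisk is a subset of weak).
#'
#' @param rnaDose1 data.frame from [tmmNbLrt()] for RNA dose1 vs control
#' @param atacWashout data.frame for ATAC dose1+0h vs washout (features
#'   keyed by gene)
#' @param rnaDose2 optional data.frame for RNA dose2 vs dose1
#' @param rnaP,rnaFdr RNA significance thresholds (default 0.05, 0.05)
#' @param atacLfc,atacFdr chromatin stability thresholds (default 0.5,
#'   0.05: |logFC| < 0.5 and FDR > 0.05)
#' @return data.frame per gene: `upOnDose1`, `accessibilityStable`,
#'   `memory`, and with dose-2 input `furtherUpWeak` / `furtherUpAsterisk`.
#' @export
classifyMemory <- function(rnaDose1, atacWashout, rnaDose2 = NULL,
                           rnaP = 0.05, rnaFdr = 0.05,
                           atacLfc = 0.5, atacFdr = 0.05) {
  genes <- intersect(rnaDose1$feature, atacWashout$feature)
  r1 <- rnaDose1[match(genes, rnaDose1$feature), ]
  at <- atacWashout[match(genes, atacWashout$feature), ]
  up1 <- r1$logFC > 0 & r1$p < rnaP & r1$fdr < rnaFdr
  stable <- abs(at$logFC) < atacLfc & at$fdr > atacFdr
  out <- data.frame(gene = genes, upOnDose1 = up1,
                    accessibilityStable = stable,
                    memory = up1 & stable, stringsAsFactors = FALSE)
  if (!is.null(rnaDose2)) {
    r2 <- rnaDose2[match(genes, rnaDose2$feature), ]
    weak <- out$memory & !is.na(r2$p) & r2$logFC > 0 & r2$p < rnaP
    ast <- weak & r2$fdr < rnaFdr
    out$furtherUpWeak <- weak
    out$furtherUpAsterisk <- ast
  }
  out
}
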