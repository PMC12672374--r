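# Independent oracles used by the unit tests: straightforward, loop-based
# recomputations of each operation's definition.

# all-pairs Pearson linking with cor.test p-values
oracleLinkPeaks <- function(expr, access, peaks, genes, maxDist = 50000,
                            minCells = 10, pMax = 0.05) {
  expr <- as.matrix(expr); access <- as.matrix(access)
  out <- NULL
  for (g in rownames(expr)) {
    for (p in rownames(access)) {
      if (as.character(GenomicRanges::seqnames(peaks[p])) !=
          as.character(GenomicRanges::seqnames(genes[g]))) next
      center <- floor((GenomicRanges::start(peaks[p]) +
                       GenomicRanges::end(peaks[p])) / 2)
      dist <- center - genes[g]$tss
      if (abs(dist) > maxDist) next
      if (sum(access[p, ] != 0) < minCells) next
      if (sd(expr[g, ]) == 0 || sd(access[p, ]) == 0) next
      ct <- suppressWarnings(cor.test(expr[g, ], access[p, ]))
      if (ct$estimate > 0 && ct$p.value < pMax)
        out <- rbind(out, data.frame(peak = p, gene = g,
                                     r = unname(ct$estimate),
                                     p = ct$p.value, distance = dist))
    }
  }
  out
}

# brute-force module score mirroring the documented procedure (bins on the
# rank of average expression, set-excluded control pools, same RNG stream)
oracleModuleScore <- function(norm, geneSet, nBins = 24, nCtrl = 100,
                              seed = 1L) {
  norm <- as.matrix(norm)
  present <- intersect(geneSet, rownames(norm))
  avg <- rowMeans(norm)
  set.seed(as.integer(seed))
  rk <- rank(avg, ties.method = "random")
  bins <- cut(rk, breaks = nBins, labels = FALSE, include.lowest = TRUE)
  names(bins) <- names(avg)
  isSet <- names(bins) %in% present
  ctrl <- integer(0)
  for (g in present) {
    halo <- 0L
    repeat {
      pool <- which(abs(bins - bins[g]) <= halo & !isSet)
      if (length(pool) >= min(nCtrl, sum(!isSet)) || halo > nBins) break
      halo <- halo + 1L
    }
    ctrl <- c(ctrl, sample(pool, min(nCtrl, length(pool))))
  }
  scores <- numeric(ncol(norm))
  for (j in seq_len(ncol(norm)))
    scores[j] <- mean(norm[present, j]) - mean(norm[ctrl, j])
  setNames(scores, colnames(norm))
}

# all-pairs interval overlap counting
oracleCountRegions <- function(fragments, regions) {
  vapply(seq_along(regions), function(i) {
    sum(vapply(seq_along(fragments), function(j) {
      as.character(GenomicRanges::seqnames(fragments[j])) ==
        as.character(GenomicRanges::seqnames(regions[i])) &&
        GenomicRanges::start(fragments[j]) <= GenomicRanges::end(regions[i]) &&
        GenomicRanges::end(fragments[j]) >= GenomicRanges::start(regions[i])
    }, logical(1)))
  }, numeric(1))
}

# brute-force gene activity: per gene, sum counts of peaks overlapping the
# body extended 500 bp upstream of the strand-aware TSS
oracleGeneActivity <- function(dataset, upstream = 500) {
  genes <- geneRanges(dataset); peaks <- peakRanges(dataset)
  atac <- as.matrix(atacCounts(dataset))
  act <- matrix(0, nrow = length(genes), ncol = ncol(atac),
                dimnames = list(names(genes), colnames(atac)))
  for (g in seq_along(genes)) {
    st <- GenomicRanges::start(genes[g]); en <- GenomicRanges::end(genes[g])
    if (as.character(GenomicRanges::strand(genes[g])) == "+") st <- st - upstream
    else en <- en + upstream
    for (p in seq_along(peaks)) {
      if (as.character(GenomicRanges::seqnames(peaks[p])) !=
          as.character(GenomicRanges::seqnames(genes[g]))) next
      if (GenomicRanges::start(peaks[p]) <= en &&
          GenomicRanges::end(peaks[p]) >= st)
        act[g, ] <- act[g, ] + atac[p, ]
    }
  }
  act
}
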