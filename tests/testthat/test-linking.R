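makeLinkFixture <- function(nGenes = 5, nPeaks = 40, nCells = 80, seed = 8) {
  set.seed(seed)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(100000, by = 200000, length.out = nGenes),
                     width = 10000), strand = "+")
  names(genes) <- paste0("g", seq_len(nGenes))
  genes$tss <- GenomicRanges::start(genes)
  centers <- unlist(lapply(genes$tss, function(t)
    t + sample(seq(-60000, 60000, by = 5000), nPeaks / nGenes)))
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(centers - 200, centers + 199))
  names(peaks) <- paste0("p", seq_along(peaks))
  expr <- matrix(rnorm(nGenes * nCells, 2), nrow = nGenes,
                 dimnames = list(names(genes), paste0("c", seq_len(nCells))))
  acc <- matrix(rnorm(length(peaks) * nCells, 1), nrow = length(peaks),
                dimnames = list(names(peaks), colnames(expr)))
  # plant a perfect and a negative association on in-window peaks
  inWin <- which(abs(centers - genes$tss[1]) <= 50000 &
                 as.character(GenomicRanges::seqnames(peaks)) == "chr1")
  acc[inWin[1], ] <- expr["g1", ]              # r = 1
  acc[inWin[2], ] <- -expr["g1", ] + rnorm(nCells, 0, 0.1)  # r ~ -1
  list(expr = expr, acc = acc, peaks = peaks, genes = genes,
       planted = rownames(acc)[inWin[1:2]])
}

test_that("linkPeaks agrees with the dense brute-force oracle", {
  fx <- makeLinkFixture()
  got <- linkPeaks(fx$expr, fx$acc, fx$peaks, fx$genes, minCells = 5)
  want <- oracleLinkPeaks(fx$expr, fx$acc, fx$peaks, fx$genes, minCells = 5)
  keyG <- paste(got$peak, got$gene)
  keyW <- paste(want$peak, want$gene)
  expect_setequal(keyG, keyW)
  m <- match(keyW, keyG)
  expect_equal(got$r[m], want$r, tolerance = 1e-10)
  expect_equal(got$p[m], want$p, tolerance = 1e-10)
  expect_equal(got$distance[m], want$distance)
})

test_that("link retention enforces window, positivity and detection rules", {
  fx <- makeLinkFixture()
  links <- linkPeaks(fx$expr, fx$acc, fx$peaks, fx$genes, minCells = 5)
  expect_true(fx$planted[1] %in% links$peak)        # r = 1 within 50 kb
  expect_false(fx$planted[2] %in% links$peak)       # negative r excluded
  expect_true(all(links$r > 0))
  expect_true(all(abs(links$distance) <= 50000))
  # r = 1 peak moved beyond the window is not linked
  peaks2 <- fx$peaks
  idx <- match(fx$planted[1], names(peaks2))
  peaks2[idx] <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(fx$genes$tss[1] + 60000 - 200,
                     fx$genes$tss[1] + 60000 + 199))
  names(peaks2)[idx] <- fx$planted[1]
  links2 <- linkPeaks(fx$expr, fx$acc, peaks2, fx$genes, minCells = 5)
  expect_false(fx$planted[1] %in% links2$peak)
  # min-cells detection floor
  accSparse <- fx$acc
  accSparse[fx$planted[1], ] <- 0
  accSparse[fx$planted[1], 1:5] <- fx$expr["g1", 1:5]
  links3 <- linkPeaks(fx$expr, accSparse, fx$peaks, fx$genes, minCells = 10)
  expect_false(fx$planted[1] %in% links3$peak)
})

test_that("enhancer scores are fragment fractions times the scale factor", {
  atac <- matrix(c(5, 10,
                   95, 40,
                   0, 50), nrow = 3, byrow = TRUE,
                 dimnames = list(c("pa", "pb", "pc"), c("c1", "c2")))
  links <- data.frame(peak = c("pa", "pb"), gene = c("gX", "gY"))
  sc <- enhancerScore(atac, links)
  expect_equal(sc["gX", "c1"], 5 / 100 * 1e4)   # 500
  expect_equal(sc["gY", "c1"], 95 / 100 * 1e4)
  expect_equal(sc["gX", "c2"], 10 / 100 * 1e4)
  # disjoint link sets: per-cell score total never exceeds the scale factor
  expect_true(all(colSums(sc) <= 1e4 + 1e-9))
  # zero-fragment cell flagged
  atac0 <- atac; atac0[, 2] <- 0
  sc0 <- enhancerScore(atac0, links)
  expect_identical(attr(sc0, "flagged"), "c2")
  expect_true(all(is.na(sc0[, "c2"])))
})

test_that("DORC definition applies the five-link rule and nests windows", {
  sim <- simulateMultiome(simConfig(nCellsPerSample = 50, seed = 6L))
  d <- sim$dataset; tr <- sim$truth
  norm <- logNormalize(rnaCounts(d))
  tfn <- tfidfNormalize(atacCounts(d))
  dg <- tr$dorcGenes
  links <- linkPeaks(norm[dg, , drop = FALSE], tfn, peakRanges(d),
                     geneRanges(d)[dg], padjMax = 0.05)
  dorc <- defineDorcs(links, norm[dg, , drop = FALSE], tfn, peakRanges(d),
                      geneRanges(d)[dg], atacCounts(d), padjMax = 0.05)
  tab <- dorc$genes
  # planted genes with >= 5 near peaks are DORCs; the 4-peak gene is not
  expect_true(all(tab$dorc[tab$nLinks50 >= 5]))
  expect_false(any(tab$dorc[tab$gene == "Dorc4"]))
  # expanded link set contains the base 50-kb links for every DORC gene
  for (g in tab$gene[tab$dorc]) {
    base <- links$peak[links$gene == g]
    expanded <- dorc$links$peak[dorc$links$gene == g]
    expect_true(all(base %in% expanded))
  }
  # far peaks only reachable at 500 kb are picked up
  far <- tr$dorcLinks$peak[tr$dorcLinks$window == "500kb" &
                           tr$dorcLinks$gene == "Dorc1"]
  expect_true(any(far %in% dorc$links$peak[dorc$links$gene == "Dorc1"]))
  # scores: zero where no linked-peak fragments
  expect_true(all(dorc$scores >= 0 | is.na(dorc$scores)))
})

test_that("binned tracks normalize away depth and group size", {
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 501), width = 100))
  names(peaks) <- c("p1", "p2")
  atac <- matrix(c(10, 0,
                   990, 1000), nrow = 2, byrow = TRUE,
                 dimnames = list(names(peaks), c("c1", "c2")))
  tr <- binnedTrack(atac, peaks, group = c("c1", "c2"), bin = 100)
  # p1 carries 10 of 2,000 fragments: value 10 * 1e4 / 2000 = 50
  expect_equal(tr$value[tr$start == 100], 50)
  # doubling every cell's counts leaves values unchanged
  tr2 <- binnedTrack(atac * 2, peaks, group = c("c1", "c2"), bin = 100)
  expect_equal(tr$value, tr2$value)
  # two groups with equal per-cell signal but different sizes match
  atac3 <- cbind(atac, c3 = atac[, "c2"])
  trA <- binnedTrack(atac3, peaks, group = "c2")
  trB <- binnedTrack(atac3, peaks, group = c("c2", "c3"))
  expect_equal(trA$value, trB$value)
  expect_error(binnedTrack(atac, peaks, group = character()), "empty")
  # bins are 0-based half-open tiles of width bin
  expect_true(all(tr$end - tr$start == 100))
})
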