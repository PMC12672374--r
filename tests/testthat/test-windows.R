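grTss <- function(pos, strand = "+", gene = NULL, chrom = "chr1") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                              strand = strand)
  g$gene <- if (is.null(gene)) paste0("g", seq_along(pos)) else gene
  g
}

test_that("a lone TSS yields a centered 1-kb window", {
  w <- buildTssWindows(grTss(10000))
  # +/-25 bp seed resized to 1 kb around its center
  expect_equal(GenomicRanges::start(w), 10000 - 499)
  expect_equal(GenomicRanges::end(w), 10000 + 500)
  expect_equal(GenomicRanges::width(w), 1000)
  expect_identical(w$gene, "g1")
})

test_that("nearby same-strand TSSs merge into one window", {
  w <- buildTssWindows(grTss(c(10000, 10030)))
  expect_length(w, 1)
  # merged seed [9975, 10055], center 10015
  expect_equal(GenomicRanges::start(w), 10015 - 499)
  expect_equal(w$n_tss, 2L)
  # 600-bp-apart TSSs: separate seeds whose 1-kb windows overlap -> merged
  w2 <- buildTssWindows(grTss(c(20000, 20600)))
  expect_length(w2, 1)
  expect_gt(GenomicRanges::width(w2), 1000)  # composite may exceed 1 kb
})

test_that("the 12-TSS toy annotation gives the hand-enumerated window set", {
  pos <- c(5000, 5040,          # same-strand pair 40 bp apart -> one window
           20000, 20600,        # 600 bp apart -> windows merge after resize
           40000,               # isolated
           60000, 64000,        # isolated pair, far apart
           80000, 80020, 80040, # triple
           100000,              # isolated, minus strand
           120000)              # isolated
  str <- c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-", "+")
  tss <- grTss(pos, strand = str)
  w <- buildTssWindows(tss)
  expect_length(w, 8)
  df <- as.data.frame(w)
  # hand-enumerated starts (0-based convention minus: stored 1-based)
  expect_equal(df$start, c(5020 - 499, 20000 - 499, 40000 - 499,
                           60000 - 499, 64000 - 499, 80020 - 499,
                           100000 - 499, 120000 - 499),
               ignore_attr = TRUE)
  # pairwise nonoverlap
  ov <- GenomicRanges::findOverlaps(w, w, ignore.strand = TRUE)
  expect_equal(length(ov), length(w))  # self-hits only
  # every window gets its closest gene
  expect_equal(df$gene[1], "g1")
  expect_equal(df$n_tss[6], 3L)
})

test_that("window sets are nonoverlapping for random annotations", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    pos <- sort(sample(seq(1000, 2e5, by = 10), n))
    str <- sample(c("+", "-"), n, replace = TRUE)
    w <- buildTssWindows(grTss(pos, strand = str))
    ov <- GenomicRanges::findOverlaps(w, w, ignore.strand = TRUE)
    expect_equal(length(ov), length(w))
  }
})

test_that("strandless TSSs and missing gene columns are rejected", {
  g <- grTss(1000, strand = "*")
  expect_error(buildTssWindows(g), "strand")
  g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1000),
                               strand = "+")
  expect_error(buildTssWindows(g2), "gene")
})

test_that("enhancer regions exclude TSS overlap and require peak support", {
  tssW <- buildTssWindows(grTss(c(10000, 50000)))
  ccres <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(10400, 30000, 31000, 70000, 90000, 110000),
    width = c(200, 300, 300, 200, 200, 200)))
  # 10400-10599 overlaps the first TSS window ([9501,10500]) by 101 bp
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(30100, 70050), width = 100))
  enh <- buildEnhancerRegions(ccres, tssW, peaks)
  df <- as.data.frame(enh)
  # cCRE overlapping a TSS window removed; 90k/110k unsupported removed;
  # 30000/31000 merge into one seed, then one 1-kb region; 70000 kept
  expect_length(enh, 2)
  expect_true(all(GenomicRanges::countOverlaps(enh, peaks) > 0))
  ov <- GenomicRanges::findOverlaps(enh, enh)
  expect_equal(length(ov), length(enh))
  expect_warning(buildEnhancerRegions(GenomicRanges::GRanges(), tssW, peaks),
                 "empty")
  # gene assignment through a peak-to-gene table
  p2g <- data.frame(peak = "pkA", gene = "geneZ")
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(30100, 30200))
  names(pk) <- "pkA"
  enh2 <- buildEnhancerRegions(ccres, tssW, peaks, peakToGene = p2g,
                               peaks = pk)
  expect_true("geneZ" %in% enh2$genes)
})

test_that("fragment counting matches the all-pairs oracle with any-overlap", {
  set.seed(31)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 1000, length.out = 20), width = 1000))
  names(regions) <- paste0("w", 1:20)
  frags <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample(500:21000, 100), width = sample(50:400, 100,
                                                            replace = TRUE)))
  got <- countRegions(list(s1 = frags), regions)
  expect_equal(unname(got[, 1]), oracleCountRegions(frags, regions))
  # a fragment spanning two adjacent regions counts in both
  span <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1950, 2050))
  both <- countRegions(span, regions[1:2])
  expect_equal(unname(both[, 1]), c(1L, 1L))
  inside <- countRegions(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(1200, 1300)), regions[1:2])
  expect_equal(unname(inside[, 1]), c(1L, 0L))
})

test_that("TMM factors are near one for equal libraries and effects recover", {
  set.seed(17)
  mu <- rlnorm(2000, log(100), 0.8)
  counts <- matrix(rnbinom(2000 * 6, size = 300, mu = rep(mu, 6)),
                   nrow = 2000,
                   dimnames = list(paste0("g", 1:2000), paste0("s", 1:6)))
  cond <- rep(c("ctrl", "d1"), each = 3)
  res <- tmmNbLrt(counts, cond, contrast = c("d1", "ctrl"))
  expect_true(all(abs(attr(res, "normFactors") - 1) < 0.01))
  expect_lte(mean(res$p < 0.05), 0.08)   # null calibration
  # planted 4-fold change
  counts2 <- counts
  counts2[1:40, 4:6] <- matrix(rnbinom(40 * 3, size = 300,
                                       mu = rep(mu[1:40] * 4, 3)), nrow = 40)
  res2 <- tmmNbLrt(counts2, cond, replicate = rep(paste0("r", 1:3), 2),
                   contrast = c("d1", "ctrl"))
  hit <- res2$feature %in% paste0("g", 1:40)
  expect_lt(abs(mean(res2$logFC[hit]) - 2), 0.3)
  expect_gt(mean(res2$fdr[hit] < 0.05), 0.9)
  expect_error(tmmNbLrt(counts[, 1:3], c("a", "a", "b"), contrast = c("b", "a")),
               "2 replicates")
})

test_that("memory gating applies the published thresholds", {
  rna1 <- data.frame(feature = paste0("g", 1:10),
                     logFC = c(2, 2, 2, 0.1, -2, 2, 2, 2, 2, 2),
                     logCPM = 5,
                     p = c(0.001, 0.001, 0.2, 0.001, 0.001, 0.001, 0.001,
                           0.001, 0.001, 0.001),
                     fdr = c(0.004, 0.004, 0.5, 0.004, 0.004, 0.004, 0.004,
                             0.004, 0.004, 0.06))
  atacW <- data.frame(feature = paste0("g", 1:10),
                      logFC = c(0.2, 0.8, 0.1, 0.1, 0.1, -0.2, 0.4, 0.49,
                                0.1, 0.1),
                      logCPM = 5,
                      p = 0.5,
                      fdr = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6, 0.03, 0.6, 0.6,
                              0.6))
  mc <- classifyMemory(rna1, atacW)
  # g1: RNA up + stable ATAC -> memory (the worked example)
  expect_true(mc$memory[mc$gene == "g1"])
  expect_false(mc$memory[mc$gene == "g2"])   # |logFC| 0.8 >= 0.5
  expect_false(mc$memory[mc$gene == "g3"])   # RNA not significant
  expect_true(mc$memory[mc$gene == "g4"])    # sign-only rule: any up FC
  expect_false(mc$memory[mc$gene == "g5"])   # downregulated
  expect_false(mc$memory[mc$gene == "g7"])   # ATAC FDR 0.03 <= 0.05: changed
  expect_true(mc$memory[mc$gene == "g8"])    # 0.49 < 0.5 boundary passes
  expect_false(mc$memory[mc$gene == "g10"])  # RNA FDR 0.06 fails
  expect_equal(sum(mc$memory), 5)            # g1, g4, g6, g8, g9
  # dose-2 classes: asterisk subset of weak
  rna2 <- data.frame(feature = paste0("g", 1:10),
                     logFC = 1, logCPM = 5,
                     p = c(0.01, rep(0.5, 8), 0.01),
                     fdr = c(0.03, rep(0.9, 8), 0.2))
  mc2 <- classifyMemory(rna1, atacW, rna2)
  expect_true(all(mc2$furtherUpAsterisk <= mc2$furtherUpWeak))
  expect_true(mc2$furtherUpAsterisk[mc2$gene == "g1"])
})
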