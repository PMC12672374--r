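test_that("filterCells removes per-sample outliers and is idempotent", {
  # toy: one 10-cell sample, one cell at 10x the median total
  set.seed(1)
  base <- matrix(rpois(10 * 10, 5), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  base[, 10] <- base[, 10] * 10
  atac <- matrix(1L, 4, 10, dimnames = list(paste0("p", 1:4), colnames(base)))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 5000, length.out = 10), width = 1000),
    strand = "+")
  names(genes) <- rownames(base); genes$tss <- GenomicRanges::start(genes)
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1000, by = 2000, length.out = 4), width = 200))
  names(peaks) <- rownames(atac)
  cd <- S4Vectors::DataFrame(sample = rep("s1", 10),
                             timepoint = rep("naive", 10),
                             cell_type = rep("t", 10),
                             replicate = rep("r1", 10),
                             row.names = colnames(base))
  d <- MultiomeExperiment(base, atac, genes, peaks, cd)
  # max = 99th percentile of totals: the 10x cell exceeds it
  tot <- Matrix::colSums(rnaCounts(d))
  f <- filterCells(d, qcThresholds(maxRnaCounts = unname(quantile(tot, 0.99))))
  expect_false("c10" %in% rownames(cellData(f$dataset)))
  expect_equal(f$report$n_removed, 1)
  # unset thresholds: identity
  f0 <- filterCells(d, qcThresholds())
  expect_identical(rownames(cellData(f0$dataset)), colnames(base))
  # idempotence on fixed numeric thresholds
  f2 <- filterCells(f$dataset, qcThresholds(maxRnaCounts = unname(quantile(tot, 0.99))))
  expect_identical(rownames(cellData(f2$dataset)),
                   rownames(cellData(f$dataset)))
  expect_error(qcThresholds(minRnaCounts = 10, maxRnaCounts = 5), "min > max")
})

test_that("FRiP is in-peak over total fragments", {
  d <- toyDataset()
  cd <- cellData(d)
  inPeak <- Matrix::colSums(atacCounts(d))  # 6, 4, 2
  cd$total_fragments <- c(100, 4, 0)
  d2 <- MultiomeExperiment(rnaCounts(d), atacCounts(d), geneRanges(d),
                           peakRanges(d), cd)
  fr <- fripScore(d2)
  expect_equal(unname(fr$frip[1]), 0.06)
  expect_equal(unname(fr$frip[2]), 1.0)   # all fragments in peaks
  expect_true(is.na(fr$frip[3]))          # zero-total cell flagged
  expect_identical(fr$flagged, "c3")
  expect_equal(unname(fr$sampleMeans[["s1"]]), mean(c(0.06, 1.0)))
})

test_that("lognormalize matches the closed form and preserves zeros", {
  m <- matrix(c(10, 990, 0, 100), nrow = 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  n <- logNormalize(m, scaleFactor = 1e4)
  expect_equal(n["a", "x"], log(1 + 10 / 1000 * 1e4))  # ln(101) ~ 4.615
  expect_equal(n["a", "x"], 4.61512, tolerance = 1e-5)
  expect_equal(n["b", "x"], log(1 + 990 / 1000 * 1e4))
  expect_true(all((as.matrix(n) == 0) == (m == 0)))
  # scale invariance: doubling a cell's counts leaves its values unchanged
  m2 <- m; m2[, "x"] <- m2[, "x"] * 2
  expect_equal(as.matrix(logNormalize(m2))[, "x"], as.matrix(n)[, "x"])
  # monotone in the raw count within a cell
  expect_gt(n["b", "x"], n["a", "x"])
  mz <- m; mz[, 1] <- 0
  expect_error(logNormalize(mz), "zero-count")
})

test_that("tfidf matches hand-computed values on a 2x2 matrix", {
  m <- matrix(c(1, 1, 0, 1), nrow = 2,
              dimnames = list(c("p1", "p2"), c("c1", "c2")))
  # p1 detected in 1 of 2 cells: idf = 2; p2 in both: idf = 1
  n <- tfidfNormalize(m, scaleFactor = 1e4)
  expect_equal(n["p1", "c1"], log1p(1 / 2 * 2 * 1e4))
  expect_equal(n["p2", "c1"], log1p(1 / 2 * 1 * 1e4))
  expect_equal(n["p2", "c2"], log1p(1 / 1 * 1 * 1e4))
  expect_equal(as.matrix(n)["p1", "c2"], 0)  # zeros preserved
  # equal TF everywhere -> equal values across cells
  me <- matrix(c(2, 2, 2, 2), nrow = 2,
               dimnames = list(c("p1", "p2"), c("c1", "c2")))
  ne <- as.matrix(tfidfNormalize(me))
  expect_equal(ne[, 1], ne[, 2])
  expect_error(tfidfNormalize(matrix(c(0, 1, 0, 1), nrow = 2,
    dimnames = list(c("z", "p"), c("a", "b")))), "all-zero")
})

test_that("gene activity honors the 500-bp strand-aware promoter rule", {
  rna <- matrix(0, 1, 3, dimnames = list("g1", c("c1", "c2", "c3")))
  atac <- matrix(c(1, 2, 3,
                   4, 5, 6,
                   7, 8, 9), nrow = 3, byrow = TRUE,
                 dimnames = list(c("inside", "up400", "up600"),
                                 c("c1", "c2", "c3")))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 15000),
                                  strand = "+")
  names(genes) <- "g1"; genes$tss <- 10000
  peaks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(12000, 9550, 9350), width = c(100, 100, 100)))
  # centers: inside body; 400 bp upstream; 600 bp upstream
  names(peaks) <- rownames(atac)
  cd <- S4Vectors::DataFrame(sample = rep("s", 3), row.names = colnames(rna))
  d <- MultiomeExperiment(rna, atac, genes, peaks, cd)
  act <- geneActivity(d, normalize = FALSE)
  # inside + up400 counted, up600 (ends at 9450 < 9500) not
  expect_equal(unname(as.matrix(act)["g1", ]), c(1 + 4, 2 + 5, 3 + 6))
  # missing strand errors
  GenomicRanges::strand(genes) <- "*"
  d2 <- MultiomeExperiment(rna, atac, genes, peaks, cd)
  expect_error(geneActivity(d2), "strand")
})

test_that("gene activity equals the brute-force interval oracle", {
  sim <- simulateMultiome(simConfig(nCellsPerSample = 5, seed = 21L))
  d <- sim$dataset
  keepG <- names(geneRanges(d))[1:10]
  keepP <- names(peakRanges(d))[1:50]
  sub <- MultiomeExperiment(rnaCounts(d)[keepG, ], atacCounts(d)[keepP, ],
                            geneRanges(d)[keepG], peakRanges(d)[keepP],
                            cellData(d))
  expect_equal(as.matrix(geneActivity(sub, normalize = FALSE)),
               oracleGeneActivity(sub))
})

test_that("variable-feature selection ranks planted structure first", {
  sim <- smallSim()
  d <- sim$dataset
  vf <- selectVariableFeatures(rnaCounts(d), n = 50,
                               atacCounts = atacCounts(d))
  # genes carrying planted structure (programs, sex markers, TF drivers
  # and their targets) dominate the top of the variability ranking
  planted <- c(sim$truth$programGenes, sim$truth$damageGenes,
               sim$truth$sexGenes$x, sim$truth$sexGenes$y,
               sim$truth$dorcGenes, sim$truth$tf$driver,
               sim$truth$tf$targets, unlist(sim$truth$tf$decoys))
  expect_gt(sum(vf$genes %in% planted), 40)
  expect_error(selectVariableFeatures(rnaCounts(d), n = 1e6), "exceeds")
  # constant gene never selected when any gene varies
  m <- rbind(const = rep(5, 20),
             matrix(rpois(100 * 20, 5), nrow = 100,
                    dimnames = list(paste0("v", 1:100), NULL)))
  colnames(m) <- paste0("c", 1:20)
  vf2 <- selectVariableFeatures(m, n = 50)
  expect_false("const" %in% vf2$genes)
  # common peaks selected at the 95% commonness rule
  a <- matrix(0, 100, 50, dimnames = list(paste0("p", 1:100),
                                          paste0("c", 1:50)))
  a[1, 1:48] <- 1            # present in 96% of cells
  for (i in 2:100) a[i, seq_len(25)] <- 1
  vf3 <- selectVariableFeatures(m[1:100, 1:20], n = 10, atacCounts = a)
  expect_true("p1" %in% vf3$peaks)
})

test_that("standardization is exact, idempotent and zeroes constants", {
  x <- matrix(c(1, 2, 3), nrow = 1)
  s <- standardizeRows(x)
  expect_equal(as.numeric(s), c(-1, 0, 1))  # sample (n-1) sd
  x2 <- rbind(x, c(4, 4, 4))
  s2 <- standardizeRows(x2)
  expect_equal(unname(s2[2, ]), c(0, 0, 0))
  expect_equal(standardizeRows(s2), s2, tolerance = 1e-8)
  # clipping
  y <- matrix(c(rep(0, 200), 1e6), nrow = 1)
  expect_lte(max(standardizeRows(y, clip = 10)), 10)
})
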