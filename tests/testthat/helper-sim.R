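# Shared small simulated dataset, built once per test run.
.simCache <- new.env(parent = emptyenv())

smallSim <- function() {
  if (is.null(.simCache$small))
    .simCache$small <- simulateMultiome(simConfig(nCellsPerSample = 60,
                                                  seed = 42L))
  .simCache$small
}

# toy MultiomeExperiment with fully controlled numbers
toyDataset <- function() {
  rna <- matrix(c(5, 0, 2,
                  1, 3, 0,
                  0, 2, 4), nrow = 3, byrow = TRUE,
                dimnames = list(c("gA", "gB", "gC"), c("c1", "c2", "c3")))
  atac <- matrix(c(2, 0, 1,
                   0, 1, 0,
                   3, 2, 0,
                   1, 1, 1), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("p", 1:4), c("c1", "c2", "c3")))
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(1000, 6000, 1000), end = c(2000, 7000, 2000)),
    strand = c("+", "-", "+"))
  names(genes) <- rownames(rna)
  genes$tss <- c(1000, 7000, 1000)
  peaks <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2", "chr2"),
    IRanges::IRanges(start = c(1100, 5500, 500, 1500),
                     end = c(1200, 5600, 700, 1600)))
  names(peaks) <- rownames(atac)
  cd <- S4Vectors::DataFrame(sample = c("s1", "s1", "s2"),
                             replicate = c("r1", "r1", "r2"),
                             timepoint = c("naive", "naive", "early"),
                             cell_type = "MOL2",
                             row.names = colnames(rna))
  MultiomeExperiment(rna = rna, atac = atac, genes = genes, peaks = peaks,
                     colData = cd)
}
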