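#' @importFrom Matrix writeMM readMM colSums rowSums rowMeans t
#' @importFrom utils write.table read.table
NULL

## MatrixMarket via Matrix::writeMM, with the header field set to
## "integer" (the values are integer counts and print without decimals).
.writeCountsMM <- function(m, path) {
  Matrix::writeMM(m, path)
  lines <- readLines(path)
  lines[1] <- sub(" real ", " integer ", lines[1], fixed = TRUE)
  writeLines(lines, path)
  invisible(path)
}

#' Write a MultiomeExperiment to a plain-text fixture directory
#'
#' Emits the on-disk exchange format used by the package: a single
#' MatrixMarket `matrix.mtx` whose rows are genes followed by peaks,
#' `genes.tsv` / `peaks.tsv` / `barcodes.tsv` row and column indexes,
#' `peaks.bed` (BED3+name, 0-based half-open), `genes.gtf` (GTF2.2,
#' 1-based inclusive), and `cells.tsv` metadata. When `truth` is supplied
#' it is serialized to `truth.json`.
#'
#' @param dataset a [MultiomeExperiment-class]
#' @param dir output directory (created if needed)
#' @param truth optional ground-truth ledger to serialize alongside
#' @return `dir`, invisibly.
#' @seealso [readMultiomeFixture()] for the exact inverse.
#' @export
writeMultiomeFixture <- function(dataset, dir, truth = NULL) {
  stopifnot(methods::is(dataset, "MultiomeExperiment"))
  if (nrow(rnaCounts(dataset)) == 0 || ncol(rnaCounts(dataset)) == 0)
    stop("refusing to write an empty dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)

  combined <- rbind(rnaCounts(dataset), atacCounts(dataset))
  .writeCountsMM(combined, file.path(dir, "matrix.mtx"))
  writeLines(rownames(rnaCounts(dataset)), file.path(dir, "genes.tsv"))
  writeLines(rownames(atacCounts(dataset)), file.path(dir, "peaks.tsv"))
  writeLines(colnames(rnaCounts(dataset)), file.path(dir, "barcodes.tsv"))

  pk <- peakRanges(dataset)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(pk)),
                    start = as.integer(GenomicRanges::start(pk)) - 1L,
                    end = as.integer(GenomicRanges::end(pk)),
                    name = names(pk))  # BED: 0-based half-open
  write.table(bed, file.path(dir, "peaks.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  gr <- geneRanges(dataset)
  gtf <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    source = "olgstate", feature = "gene",
    start = as.integer(GenomicRanges::start(gr)),  # GTF: 1-based inclusive
    end = as.integer(GenomicRanges::end(gr)),
    score = ".", strand = as.character(GenomicRanges::strand(gr)),
    frame = ".",
    attribute = sprintf('gene_id "%s"; tss "%d";', names(gr),
                        as.integer(gr$tss)))
  write.table(gtf, file.path(dir, "genes.gtf"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)

  cells <- as.data.frame(cellData(dataset))
  cells <- cbind(cell = rownames(cells), cells)
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture directory back into a MultiomeExperiment
#'
#' Exact inverse of [writeMultiomeFixture()]; a written dataset reads back
#' equal to the original (matrices, coordinates, metadata).
#'
#' @param dir fixture directory
#' @return list with `dataset` and (when `truth.json` is present) `truth`.
#' @export
readMultiomeFixture <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  m <- methods::as(m, "dgCMatrix")
  geneIds <- readLines(file.path(dir, "genes.tsv"))
  peakIds <- readLines(file.path(dir, "peaks.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  stopifnot(nrow(m) == length(geneIds) + length(peakIds))
  rownames(m) <- c(geneIds, peakIds)
  colnames(m) <- barcodes
  rna <- m[seq_along(geneIds), , drop = FALSE]
  atac <- m[length(geneIds) + seq_along(peakIds), , drop = FALSE]

  bed <- read.table(file.path(dir, "peaks.bed"), sep = "\t", quote = "",
                    comment.char = "",
                    col.names = c("chrom", "start", "end", "name"))
  peaks <- GRanges(bed$chrom, IRanges(bed$start + 1L, bed$end))  # to 1-based
  names(peaks) <- bed$name

  gtf <- read.table(file.path(dir, "genes.gtf"), sep = "\t", quote = "",
                    comment.char = "",
                    col.names = c("seqname", "source", "feature", "start",
                                  "end", "score", "strand", "frame",
                                  "attribute"))
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", gtf$attribute)
  tss <- as.integer(sub('.*tss "([0-9]+)".*', "\\1", gtf$attribute))
  genes <- GRanges(gtf$seqname, IRanges(gtf$start, gtf$end),
                   strand = gtf$strand)
  names(genes) <- gid
  genes$tss <- tss

  cells <- read.table(file.path(dir, "cells.tsv"), sep = "\t", header = TRUE,
                      colClasses = c(cell = "character"))
  colData <- S4Vectors::DataFrame(cells[, -1, drop = FALSE],
                                  row.names = cells$cell)
  dataset <- MultiomeExperiment(rna = rna, atac = atac, genes = genes,
                                peaks = peaks, colData = colData)
  out <- list(dataset = dataset)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  out
}
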