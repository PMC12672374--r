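#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom S4Vectors DataFrame DFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Disease-stage levels
#'
#' Canonical ordering of the experimental conditions: two control arms
#' (naive, adjuvant-only "cfa") followed by the early, peak and late disease
#' stages. All stage-aware functions in the package order factors this way.
#'
#' @return Character vector of stage names.
#' @export
stageLevels <- function() c("naive", "cfa", "early", "peak", "late")

#' MultiomeExperiment: paired single-cell RNA + ATAC container
#'
#' Holds a gene-by-cell RNA count matrix and a peak-by-cell ATAC count
#' matrix over a shared set of cells, together with the peak intervals,
#' the gene annotation (including the strand-aware TSS) and per-cell
#' metadata. Columns of both matrices are keyed by the rownames of
#' `colData`; rows are keyed by the names of `genes` / `peaks`.
#'
#' @slot rna sparse integer matrix, genes x cells
#' @slot atac sparse integer matrix, peaks x cells
#' @slot genes `GRanges` of gene bodies with metadata column `tss`
#' @slot peaks `GRanges` of peak intervals
#' @slot colData `DataFrame` of per-cell metadata (sample, replicate,
#'   timepoint, cell_type, and optionally sex, embedding coordinates,
#'   total_fragments)
#'
#' @aliases MultiomeExperiment
#' @export
setClass("MultiomeExperiment",
  slots = c(
    rna     = "dgCMatrix",
    atac    = "dgCMatrix",
    genes   = "GRanges",
    peaks   = "GRanges",
    colData = "DFrame"
  )
)

setValidity("MultiomeExperiment", function(object) {
  msg <- character()
  nm <- function(x) if (is.null(x)) character(0) else as.character(x)
  if (ncol(object@rna) != nrow(object@colData))
    msg <- c(msg, "ncol(rna) must equal nrow(colData)")
  if (ncol(object@atac) != nrow(object@colData))
    msg <- c(msg, "ncol(atac) must equal nrow(colData)")
  if (nrow(object@rna) != length(object@genes))
    msg <- c(msg, "nrow(rna) must equal length(genes)")
  if (nrow(object@atac) != length(object@peaks))
    msg <- c(msg, "nrow(atac) must equal length(peaks)")
  if (is.null(rownames(object@colData)) && nrow(object@colData) > 0)
    msg <- c(msg, "colData must have rownames (cell barcodes)")
  if (!identical(nm(colnames(object@rna)), nm(rownames(object@colData))) ||
      !identical(nm(colnames(object@atac)), nm(rownames(object@colData))))
    msg <- c(msg, "matrix colnames must match colData rownames")
  if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
    msg <- c(msg, "genes must have unique names")
  if (is.null(names(object@peaks)) || anyDuplicated(names(object@peaks)))
    msg <- c(msg, "peaks must have unique names")
  if (!identical(rownames(object@rna), names(object@genes)))
    msg <- c(msg, "rna rownames must match gene names")
  if (!identical(rownames(object@atac), names(object@peaks)))
    msg <- c(msg, "atac rownames must match peak names")
  if (length(object@rna@x) && min(object@rna@x) < 0)
    msg <- c(msg, "rna counts must be non-negative")
  if (length(object@atac@x) && min(object@atac@x) < 0)
    msg <- c(msg, "atac counts must be non-negative")
  if (is.null(object@genes$tss))
    msg <- c(msg, "genes must carry a 'tss' metadata column")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiomeExperiment
#'
#' @param rna genes x cells count matrix (coerced to sparse)
#' @param atac peaks x cells count matrix (coerced to sparse)
#' @param genes named `GRanges` of gene bodies; if no `tss` metadata column
#'   is present it is derived from the strand (start for `+`, end for `-`)
#' @param peaks named `GRanges` of peaks
#' @param colData per-cell metadata with rownames = cell barcodes
#' @return A [MultiomeExperiment-class] object.
#' @examples
#' sim <- simulateMultiome(simConfig(nCellsPerSample = 20, seed = 1))
#' sim$dataset
#' @export
MultiomeExperiment <- function(rna, atac, genes, peaks, colData) {
  rna <- methods::as(methods::as(rna, "CsparseMatrix"), "dgCMatrix")
  atac <- methods::as(methods::as(atac, "CsparseMatrix"), "dgCMatrix")
  if (!methods::is(colData, "DFrame")) colData <- S4Vectors::DataFrame(colData)
  if (is.null(genes$tss)) {
    genes$tss <- ifelse(as.character(strand(genes)) == "-",
                        end(genes), start(genes))
  }
  methods::new("MultiomeExperiment", rna = rna, atac = atac,
               genes = genes, peaks = peaks, colData = colData)
}

setMethod("show", "MultiomeExperiment", function(object) {
  cat("class: MultiomeExperiment\n")
  cat(sprintf("rna: %d genes x %d cells\n", nrow(object@rna), ncol(object@rna)))
  cat(sprintf("atac: %d peaks x %d cells\n", nrow(object@atac), ncol(object@atac)))
  cat("colData columns:", paste(colnames(object@colData), collapse = ", "), "\n")
  tp <- object@colData$timepoint
  if (!is.null(tp)) {
    tab <- table(factor(tp, levels = intersect(stageLevels(), unique(tp))))
    cat("timepoints:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
})

#' @rdname MultiomeExperiment
#' @param object,x a `MultiomeExperiment`
#' @export
setGeneric("rnaCounts", function(object) standardGeneric("rnaCounts"))
#' @rdname MultiomeExperiment
#' @export
setMethod("rnaCounts", "MultiomeExperiment", function(object) object@rna)

#' @rdname MultiomeExperiment
#' @export
setGeneric("atacCounts", function(object) standardGeneric("atacCounts"))
#' @rdname MultiomeExperiment
#' @export
setMethod("atacCounts", "MultiomeExperiment", function(object) object@atac)

#' @rdname MultiomeExperiment
#' @export
setGeneric("geneRanges", function(object) standardGeneric("geneRanges"))
#' @rdname MultiomeExperiment
#' @export
setMethod("geneRanges", "MultiomeExperiment", function(object) object@genes)

#' @rdname MultiomeExperiment
#' @export
setGeneric("peakRanges", function(object) standardGeneric("peakRanges"))
#' @rdname MultiomeExperiment
#' @export
setMethod("peakRanges", "MultiomeExperiment", function(object) object@peaks)

#' @rdname MultiomeExperiment
#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))
#' @rdname MultiomeExperiment
#' @export
setMethod("cellData", "MultiomeExperiment", function(object) object@colData)

#' @rdname MultiomeExperiment
#' @param i cell index, logical mask or barcode vector
#' @param j,drop,... ignored (cell-wise subsetting only)
#' @export
setMethod("[", "MultiomeExperiment", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, rownames(x@colData))
  methods::new("MultiomeExperiment",
               rna = x@rna[, i, drop = FALSE],
               atac = x@atac[, i, drop = FALSE],
               genes = x@genes, peaks = x@peaks,
               colData = x@colData[i, , drop = FALSE])
})

#' @rdname MultiomeExperiment
#' @export
setMethod("dim", "MultiomeExperiment", function(x) {
  c(nrow(x@rna) + nrow(x@atac), ncol(x@rna))
})

#' Gaussian null model for scaled module scores
#'
#' Normal distribution fitted to the scaled scores of a control cell
#' population; its CDF `F(x) = (1/2) * (1 + erf((x - mu)/(sigma sqrt(2))))`
#' supplies the per-cell tail probability used to call a status.
#'
#' @slot mu mean of control-cell scaled scores
#' @slot sigma sample (n-1) standard deviation of control-cell scaled scores
#' @slot control identifier of the control population
#' @aliases GaussianNull
#' @export
setClass("GaussianNull",
  slots = c(mu = "numeric", sigma = "numeric", control = "character"))

setValidity("GaussianNull", function(object) {
  if (length(object@mu) != 1 || length(object@sigma) != 1)
    return("mu and sigma must be scalars")
  if (!is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be a positive finite scalar")
  TRUE
})

setMethod("show", "GaussianNull", function(object) {
  cat(sprintf("GaussianNull(mu = %.4g, sigma = %.4g, control = '%s')\n",
              object@mu, object@sigma, object@control))
})

#' Evaluate the null CDF F(x)
#'
#' @param null a [GaussianNull-class]
#' @param x numeric vector of scaled scores
#' @return F(x), the lower-tail probability under the fitted normal.
#' @export
pnull <- function(null, x) {
  stopifnot(methods::is(null, "GaussianNull"))
  0.5 * (1 + erf((x - null@mu) / (null@sigma * sqrt(2))))
}

#' Error function
#'
#' erf(x) as used by the Gaussian-null CDF, expressed through [stats::pnorm].
#' @param x numeric
#' @return erf(x)
#' @export
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
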