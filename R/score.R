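#' @importFrom stats aggregate
NULL

#' Gene-set module score
#'
#' For each cell, the mean normalized expression of the set genes minus
#' the mean over matched control genes. Controls are drawn per set gene:
#' all genes are cut into `nBins` equal-frequency bins of average
#' normalized expression, and `nCtrl` control genes are sampled (seeded)
#' from the bin of each set gene, excluding the set genes themselves
#' (an empty pool widens to the nearest bins). Scores are location-invariant: adding a
#' constant to every gene leaves them unchanged.
#'
#' @param norm features x cells normalized matrix (e.g. [logNormalize()]
#'   or [geneActivity()] output)
#' @param geneSet character vector of set gene ids; members absent from
#'   the matrix are dropped (an empty intersection is an error)
#' @param nBins number of equal-frequency average-expression bins
#' @param nCtrl control genes sampled per set gene
#' @param seed seed for control sampling
#' @return named numeric vector of per-cell raw scores.
#' @export
moduleScore <- function(norm, geneSet, nBins = 24, nCtrl = 100, seed = 1L) {
  present <- intersect(geneSet, rownames(norm))
  if (length(present) == 0) stop("no gene-set members present in the matrix")
  avg <- Matrix::rowMeans(norm)
  nBinsUse <- nBins
  if (length(avg) < nBins) {
    nBinsUse <- max(2L, length(avg) %/% 2L)
    warning(sprintf("fewer genes (%d) than bins (%d); using %d bins",
                    length(avg), nBins, nBinsUse))
  }
  ## equal-frequency binning on the rank of average expression (random,
  ## seeded tie-break so bin sizes are balanced)
  set.seed(as.integer(seed))
  rk <- rank(avg, ties.method = "random")
  bins <- cut(rk, breaks = nBinsUse, labels = FALSE, include.lowest = TRUE)
  names(bins) <- names(avg)
  ## control pools exclude the set genes themselves; a pool smaller than
  ## nCtrl distinct genes widens to the nearest expression bins so every
  ## set gene draws nCtrl distinct matched controls
  isSet <- names(bins) %in% present
  nBackground <- sum(!isSet)
  if (nBackground == 0) stop("no background genes available for controls")
  ctrlIdx <- integer(0)
  for (g in present) {
    halo <- 0L
    repeat {
      pool <- which(abs(bins - bins[g]) <= halo & !isSet)
      if (length(pool) >= min(nCtrl, nBackground) || halo > nBinsUse) break
      halo <- halo + 1L
    }
    ctrlIdx <- c(ctrlIdx, sample(pool, min(nCtrl, length(pool))))
  }
  setMean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrlMean <- Matrix::colMeans(norm[ctrlIdx, , drop = FALSE])
  score <- setMean - ctrlMean
  names(score) <- colnames(norm)
  score
}

#' Min-max scale scores to \[0, 1\]
#'
#' Scales raw module scores to `(x - min) / (max - min)` within groups
#' (typically within cell type, pooling all conditions). With no grouping
#' the whole population is scaled together.
#'
#' @param score named per-cell raw scores
#' @param groups optional per-cell grouping factor (same order as `score`)
#' @return per-cell scaled scores in \[0, 1\].
#' @export
scaleScores <- function(score, groups = NULL) {
  scaleOne <- function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (is.null(groups)) return(setNames(scaleOne(score), names(score)))
  stopifnot(length(groups) == length(score))
  out <- numeric(length(score))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    out[idx] <- scaleOne(score[idx])
  }
  setNames(out, names(score))
}

#' Fit the Gaussian null from control cells
#'
#' Estimates `mu` and the sample (n-1) standard deviation `sigma` of the
#' scaled scores of the control population; the resulting
#' [GaussianNull-class] supplies F(x) = (1/2)\[1 + erf((x - mu)/(sigma
#' sqrt(2)))\].
#'
#' @param scaled named per-cell scaled scores
#' @param controlCells barcodes of the control (null) population
#' @param control label recorded on the model
#' @return a [GaussianNull-class].
#' @export
fitNull <- function(scaled, controlCells, control = "control") {
  x <- scaled[intersect(controlCells, names(scaled))]
  if (length(x) < 2) stop("need at least 2 control cells")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate null: control scores are constant")
  methods::new("GaussianNull", mu = mean(x), sigma = s, control = control)
}

#' Classify cell status against the Gaussian null
#'
#' Upper-tail probability P = 1 - F(x) of each cell's scaled score under
#' the fitted null; a cell is called positive (immune / damage) when
#' P < alpha. A score at the null mean gives P = 0.5.
#'
#' @param scaled named per-cell scaled scores
#' @param null a [GaussianNull-class]
#' @param alpha significance level (default 0.05)
#' @param labels length-2 character: positive and negative label
#' @return data.frame with `cell`, `score`, `p` and `status`.
#' @export
classifyStatus <- function(scaled, null, alpha = 0.05,
                           labels = c("immune", "nonimmune")) {
  p <- 1 - pnull(null, scaled)
  data.frame(cell = names(scaled), score = unname(scaled), p = unname(p),
             status = ifelse(p < alpha, labels[1], labels[2]),
             stringsAsFactors = FALSE)
}

#' Score and classify on either modality
#'
#' Composes [moduleScore()], [scaleScores()], [fitNull()] and
#' [classifyStatus()] per cell type: scores are scaled within cell type
#' across all pooled conditions, the null is fitted on that cell type's
#' control cells, and cells of a type with no control cells are returned
#' unlabeled (`status = NA`).
#'
#' @param norm normalized matrix of the chosen modality (expression via
#'   [logNormalize()], chromatin via [geneActivity()])
#' @param geneSet set gene ids
#' @param controlCells barcodes of the control population (e.g. naive)
#' @param cellTypes optional per-cell type factor (names = barcodes); when
#'   NULL all cells are treated as one type
#' @param alpha significance level
#' @param nBins,nCtrl,seed passed to [moduleScore()]
#' @param labels passed to [classifyStatus()]
#' @return data.frame per cell: `cell`, `cell_type`, `raw`, `score`, `p`,
#'   `status`.
#' @export
scoreStatus <- function(norm, geneSet, controlCells, cellTypes = NULL,
                        alpha = 0.05, nBins = 24, nCtrl = 100, seed = 1L,
                        labels = c("immune", "nonimmune")) {
  raw <- moduleScore(norm, geneSet, nBins = nBins, nCtrl = nCtrl, seed = seed)
  if (is.null(cellTypes))
    cellTypes <- setNames(rep("all", length(raw)), names(raw))
  cellTypes <- cellTypes[names(raw)]
  out <- NULL
  for (ct in unique(cellTypes)) {
    idx <- names(raw)[cellTypes == ct]
    scaled <- scaleScores(raw[idx])
    ctrl <- intersect(controlCells, idx)
    if (length(ctrl) < 2) {
      res <- data.frame(cell = idx, score = unname(scaled), p = NA_real_,
                        status = NA_character_, stringsAsFactors = FALSE)
    } else {
      null <- fitNull(scaled, ctrl, control = "control")
      res <- classifyStatus(scaled, null, alpha = alpha, labels = labels)
    }
    res$cell_type <- ct
    res$raw <- unname(raw[idx])
    out <- rbind(out, res)
  }
  out[match(names(raw), out$cell), c("cell", "cell_type", "raw", "score",
                                     "p", "status")]
}

#' Joint damage/IFN status
#'
#' Deterministic 2x2 combination of two status calls over the same cells:
#' `both`, `ifn_only`, `damage_only` or `neither`.
#'
#' @param ifnCall,damageCall data.frames from [classifyStatus()] /
#'   [scoreStatus()] with columns `cell` and `status`; statuses must use
#'   positive labels "immune" and "damage" respectively
#' @return data.frame with `cell` and `joint`.
#' @export
jointStatus <- function(ifnCall, damageCall) {
  if (!setequal(ifnCall$cell, damageCall$cell))
    stop("the two calls cover different cell sets")
  damageCall <- damageCall[match(ifnCall$cell, damageCall$cell), ]
  ifn <- ifnCall$status %in% c("immune", "ifn")
  dmg <- damageCall$status == "damage"
  joint <- ifelse(ifn & dmg, "both",
           ifelse(ifn, "ifn_only",
           ifelse(dmg, "damage_only", "neither")))
  joint[is.na(ifnCall$status) | is.na(damageCall$status)] <- NA
  data.frame(cell = ifnCall$cell, joint = joint, stringsAsFactors = FALSE)
}
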