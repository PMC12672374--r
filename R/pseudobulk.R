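#' @importFrom Matrix sparseMatrix
NULL

#' Aggregate single cells into pseudobulk profiles
#'
#' Sums raw counts over cells grouped by the given metadata keys (default
#' sample x cell type), records per-group cell numbers and group-level
#' metadata, and removes features with fewer than `minFeatureCount` total
#' counts.
#'
#' @param counts features x cells raw counts
#' @param cellMeta per-cell metadata (rownames = barcodes) carrying the
#'   grouping keys and, if present, `timepoint`, `replicate` and covariates
#' @param groupKeys metadata columns defining the groups
#' @param minFeatureCount features below this total are dropped (default 10)
#' @return list with `counts` (features x groups integer matrix), `groups`
#'   (one row per group: keys, `n_cells`, and any constant-within-group
#'   metadata columns) and `dropped` (removed feature ids).
#' @export
aggregatePseudobulk <- function(counts, cellMeta,
                                groupKeys = c("sample", "cell_type"),
                                minFeatureCount = 10) {
  stopifnot(all(groupKeys %in% colnames(cellMeta)))
  cellMeta <- as.data.frame(cellMeta)
  if (!is.null(rownames(cellMeta)) && !is.null(colnames(counts)))
    cellMeta <- cellMeta[colnames(counts), , drop = FALSE]
  if (nrow(cellMeta) == 0) stop("empty grouping")
  key <- do.call(paste, c(lapply(groupKeys, function(k) cellMeta[[k]]),
                          sep = "."))
  if (!length(key) || anyNA(cellMeta[[groupKeys[1]]])) stop("empty grouping")
  groups <- sort(unique(key))
  ind <- sparseMatrix(i = seq_along(key), j = match(key, groups), x = 1,
                      dims = c(length(key), length(groups)))
  agg <- as.matrix(counts %*% ind)
  agg <- matrix(as.integer(round(agg)), nrow = nrow(agg),
                dimnames = list(rownames(counts), groups))
  meta <- data.frame(group = groups, stringsAsFactors = FALSE)
  first <- match(groups, key)
  for (k in groupKeys) meta[[k]] <- cellMeta[[k]][first]
  for (k in setdiff(colnames(cellMeta), groupKeys)) {
    vals <- tapply(cellMeta[[k]], key, function(v) {
      u <- unique(v); if (length(u) == 1) u else NA
    })
    if (!all(is.na(vals))) meta[[k]] <- unname(vals[groups])
  }
  meta$n_cells <- as.integer(table(key)[groups])
  total <- rowSums(agg)
  dropped <- rownames(agg)[total < minFeatureCount]
  keep <- total >= minFeatureCount
  list(counts = agg[keep, , drop = FALSE], groups = meta, dropped = dropped)
}

#' Drop under-populated pseudobulk groups
#'
#' Removes groups (samples) with fewer than `minSampleCells` cells, then
#' removes every group of a time point whose surviving cell total is below
#' `minTimepointCells` (per cell type when a `cell_type` column exists).
#'
#' @param pb output of [aggregatePseudobulk()]
#' @param minSampleCells minimum cells per sample group (default 5)
#' @param minTimepointCells minimum cells per time point (default 30)
#' @return `pb` with offending groups removed and a `report` element.
#' @export
filterGroups <- function(pb, minSampleCells = 5, minTimepointCells = 30) {
  g <- pb$groups
  keep <- g$n_cells >= minSampleCells
  removed <- data.frame(group = g$group[!keep],
                        reason = rep("sample < minSampleCells", sum(!keep)))
  if (!is.null(g$timepoint)) {
    ctKey <- if (!is.null(g$cell_type)) g$cell_type else ""
    for (ct in unique(ctKey)) {
      for (tp in unique(g$timepoint[ctKey == ct])) {
        idx <- which(ctKey == ct & g$timepoint == tp & keep)
        if (length(idx) && sum(g$n_cells[idx]) < minTimepointCells) {
          keep[idx] <- FALSE
          removed <- rbind(removed, data.frame(
            group = g$group[idx],
            reason = rep("timepoint < minTimepointCells", length(idx))))
        }
      }
    }
  }
  list(counts = pb$counts[, keep, drop = FALSE],
       groups = g[keep, , drop = FALSE],
       dropped = pb$dropped, report = removed)
}

## resolve "control" to the control arm present in the data
.resolveLevel <- function(level, levels) {
  if (level == "control") {
    if ("cfa" %in% levels) return("cfa")
    if ("naive" %in% levels) return("naive")
  }
  level
}

#' Negative-binomial Wald differential testing on pseudobulk counts
#'
#' Fits the pseudobulk counts with DESeq2 (median-of-ratios size factors,
#' shrunk gene-wise dispersions, Wald tests, Benjamini-Hochberg adjustment
#' within contrast) under a design of time point plus an optional
#' categorical covariate, and extracts one results table per contrast.
#'
#' @param pb output of [aggregatePseudobulk()] / [filterGroups()]; its
#'   `groups` table must carry a `timepoint` column
#' @param contrasts list of `c(numerator, denominator)` time-point pairs;
#'   `"control"` resolves to the adjuvant control arm. Default: the four
#'   disease-course contrasts early/control, peak/early, late/early,
#'   peak/late.
#' @param covariate optional name of a categorical covariate column in
#'   `pb$groups` (e.g. a debris-removal batch)
#' @return data.frame with `feature`, `contrast`, `log2FC`, `p`, `padj`,
#'   `baseMean`. Contrasts with an absent level are skipped with a warning.
#' @export
nbWald <- function(pb,
                   contrasts = list(c("early", "control"),
                                    c("peak", "early"),
                                    c("late", "early"),
                                    c("peak", "late")),
                   covariate = NULL) {
  g <- pb$groups
  stopifnot(!is.null(g$timepoint))
  tps <- intersect(stageLevels(), unique(g$timepoint))
  cd <- data.frame(timepoint = factor(g$timepoint, levels = tps),
                   row.names = g$group)
  design <- ~timepoint
  if (!is.null(covariate) && covariate %in% colnames(g) &&
      length(unique(g[[covariate]])) > 1) {
    cd$covar <- factor(g[[covariate]])
    design <- ~covar + timepoint
  }
  dds <- DESeq2::DESeqDataSetFromMatrix(pb$counts, colData = cd,
                                        design = design)
  dds <- DESeq2::DESeq(dds, quiet = TRUE, minReplicatesForReplace = Inf)
  out <- NULL
  for (cn in contrasts) {
    num <- .resolveLevel(cn[1], tps)
    den <- .resolveLevel(cn[2], tps)
    if (!(num %in% tps) || !(den %in% tps)) {
      warning("contrast ", cn[1], "/", cn[2], " skipped: level absent")
      next
    }
    res <- DESeq2::results(dds, contrast = c("timepoint", num, den))
    out <- rbind(out, data.frame(
      feature = rownames(res),
      contrast = paste0(cn[1], "/", cn[2]),
      log2FC = res$log2FoldChange, p = res$pvalue, padj = res$padj,
      baseMean = res$baseMean, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Select differential features
#'
#' Union over contrasts of features with |log2FC| > `lfcMin`, adjusted
#' p < `padjMax` and baseMean > `baseMeanMin`.
#'
#' @param results data.frame from [nbWald()]
#' @param lfcMin,padjMax,baseMeanMin thresholds (defaults 1, 0.01, 1)
#' @return character vector of selected features.
#' @export
selectDifferential <- function(results, lfcMin = 1, padjMax = 0.01,
                               baseMeanMin = 1) {
  if (is.null(results) || nrow(results) == 0) return(character())
  ok <- !is.na(results$padj) & abs(results$log2FC) > lfcMin &
    results$padj < padjMax & results$baseMean > baseMeanMin
  unique(results$feature[ok])
}

#' Min-max scale temporal profiles
#'
#' Scales each feature's per-time-point means to \[0, 1\] across time
#' points; constant profiles map to all-zero (documented convention) and
#' missing values are set to 0.
#'
#' @param profiles features x timepoints numeric matrix
#' @return scaled matrix of the same shape.
#' @export
scaleDynamics <- function(profiles) {
  profiles <- as.matrix(profiles)
  profiles[is.na(profiles)] <- 0
  out <- t(apply(profiles, 1, function(x) {
    rng <- range(x)
    if (rng[2] == rng[1]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }))
  dimnames(out) <- dimnames(profiles)
  out
}

#' Temporal type assignment
#'
#' Assigns each feature the time point of its maximum 0-1-scaled mean
#' (Type 1 = control-high, 2 = early-high, 3 = peak-high, 4 = late-high,
#' following the column order), with deterministic ties broken by stage
#' order, plus an optional secondary subtype: the second-ranked time point
#' when its scaled value reaches `secondaryMin`.
#'
#' @param scaled features x timepoints matrix from [scaleDynamics()],
#'   columns in stage order (control, early, peak, late)
#' @param secondaryMin scaled-value floor for a secondary subtype
#'   (default 0.5)
#' @return data.frame with `feature`, `type` (integer), `mainStage`,
#'   `secondaryStage` (NA when none).
#' @export
assignTypes <- function(scaled, secondaryMin = 0.5) {
  scaled <- as.matrix(scaled)
  if (is.null(rownames(scaled))) rownames(scaled) <- seq_len(nrow(scaled))
  stages <- colnames(scaled)
  if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(scaled)))
  main <- apply(scaled, 1, which.max)  # first max = earliest stage on ties
  second <- integer(nrow(scaled))
  for (i in seq_len(nrow(scaled))) {
    ord <- order(scaled[i, ], -seq_len(ncol(scaled)), decreasing = TRUE)
    second[i] <- ord[2]
  }
  secOk <- scaled[cbind(seq_len(nrow(scaled)), second)] >= secondaryMin
  data.frame(feature = rownames(scaled), type = as.integer(main),
             mainStage = stages[main],
             secondaryStage = ifelse(secOk, stages[second], NA_character_),
             stringsAsFactors = FALSE)
}

#' Per-group dynamics summaries
#'
#' Mean and standard deviation of scaled profiles across the member
#' features of each group (e.g. temporal type), per time point.
#'
#' @param scaled features x timepoints scaled matrix
#' @param groups per-feature grouping vector
#' @return data.frame with `group`, `timepoint`, `mean`, `sd`.
#' @export
summarizeDynamics <- function(scaled, groups) {
  scaled <- as.matrix(scaled)
  out <- NULL
  for (g in unique(groups)) {
    sub <- scaled[groups == g, , drop = FALSE]
    out <- rbind(out, data.frame(
      group = g, timepoint = colnames(sub),
      mean = colMeans(sub), sd = apply(sub, 2, sd)))
  }
  rownames(out) <- NULL
  out
}
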