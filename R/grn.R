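#' @importFrom stats lm pf
NULL

#' Fit a regression-based gene regulatory network
#'
#' For each target gene (candidate regulatory regions are assigned to
#' their nearest TSS), fits an ordinary least squares model of the
#' target's normalized expression on the products of normalized TF
#' expression x normalized region accessibility, one predictor per
#' admissible (region, TF-with-motif-in-region) pair. Cells are subset to
#' at most `maxCellsPerTimepoint` per time point (seeded). Duplicate
#' predictor columns are dropped with a warning; targets with no
#' admissible pair are skipped and logged.
#'
#' @param expr genes x cells normalized expression
#' @param access peaks x cells normalized accessibility
#' @param candidateRegions names of the candidate peaks (e.g. the
#'   stage-differential peaks)
#' @param motifs data.frame with columns `peak`, `tf` (motif incidence)
#' @param peaks,genes `GRanges` for access/expr rows (`genes` must carry
#'   `tss`)
#' @param timepoints per-cell time point vector (names = barcodes)
#' @param maxCellsPerTimepoint subsampling cap (default 2,000)
#' @param seed subsampling seed
#' @return a `GrnModel` list: `coefficients` (data.frame target, tf, peak,
#'   estimate), `fits` (target, r2, p, padj across fitted targets),
#'   `skipped`, `cells` (the subsampled barcodes).
#' @export
fitGrn <- function(expr, access, candidateRegions, motifs, peaks, genes,
                   timepoints, maxCellsPerTimepoint = 2000, seed = 1L) {
  stopifnot(identical(colnames(expr), colnames(access)))
  timepoints <- timepoints[colnames(expr)]
  set.seed(as.integer(seed))
  keep <- unlist(lapply(split(seq_along(timepoints), timepoints), function(ix) {
    if (length(ix) > maxCellsPerTimepoint) sample(ix, maxCellsPerTimepoint)
    else ix
  }))
  keep <- sort(keep)
  expr <- expr[, keep, drop = FALSE]
  access <- access[, keep, drop = FALSE]

  candidateRegions <- intersect(candidateRegions, rownames(access))
  candidateRegions <- intersect(candidateRegions, unique(motifs$peak))
  if (!length(candidateRegions)) stop("no candidate regions with motifs")
  ## nearest-TSS assignment of regions to target genes
  pc <- .peakCenter(peaks[candidateRegions])
  pchr <- as.character(GenomicRanges::seqnames(peaks[candidateRegions]))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  assign <- vapply(seq_along(candidateRegions), function(i) {
    same <- which(gchr == pchr[i])
    if (!length(same)) return(NA_character_)
    d <- abs(genes$tss[same] - pc[i])
    cands <- names(genes)[same[d == min(d)]]
    sort(cands)[1]  # ties: lexicographically smallest gene id
  }, character(1))
  names(assign) <- candidateRegions

  coefs <- NULL; fits <- NULL; skipped <- character()
  exprD <- as.matrix(expr)
  accD <- as.matrix(access[candidateRegions, , drop = FALSE])
  for (target in unique(stats::na.omit(assign))) {
    if (!(target %in% rownames(exprD))) { skipped <- c(skipped, target); next }
    regs <- candidateRegions[assign == target & !is.na(assign)]
    pairs <- motifs[motifs$peak %in% regs & motifs$tf %in% rownames(exprD), ]
    pairs <- pairs[pairs$tf != target, , drop = FALSE]
    if (!nrow(pairs)) { skipped <- c(skipped, target); next }
    X <- sapply(seq_len(nrow(pairs)), function(k) {
      as.numeric(scale(exprD[pairs$tf[k], ])) *
        as.numeric(scale(accD[pairs$peak[k], ]))
    })
    X <- matrix(X, ncol = nrow(pairs))
    colnames(X) <- paste0(pairs$tf, ":", pairs$peak)
    dup <- duplicated(t(X)) | !apply(X, 2, function(c) sd(c) > 0)
    if (any(dup)) {
      warning("dropping ", sum(dup), " degenerate predictor(s) for ", target)
      X <- X[, !dup, drop = FALSE]
      pairs <- pairs[!dup, , drop = FALSE]
    }
    if (!ncol(X)) { skipped <- c(skipped, target); next }
    y <- exprD[target, ]
    fit <- lm(y ~ X)
    cf <- stats::coef(fit)[-1]
    cf[is.na(cf)] <- 0
    sm <- summary(fit)
    pval <- if (is.null(sm$fstatistic)) NA_real_ else
      unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE))
    coefs <- rbind(coefs, data.frame(target = target, tf = pairs$tf,
                                     peak = pairs$peak,
                                     estimate = unname(cf),
                                     stringsAsFactors = FALSE))
    fits <- rbind(fits, data.frame(target = target, r2 = sm$r.squared,
                                   p = pval, stringsAsFactors = FALSE))
  }
  if (!is.null(fits)) fits$padj <- stats::p.adjust(fits$p, method = "BH")
  structure(list(coefficients = coefs, fits = fits, skipped = skipped,
                 cells = colnames(expr)), class = "GrnModel")
}

#' Select significant GRN modules
#'
#' Retains targets whose model fit has a BH-adjusted p below `alpha` and
#' groups the surviving (TF, target) pairs by TF.
#'
#' @param model a `GrnModel` from [fitGrn()]
#' @param alpha adjusted-p threshold (default 0.05)
#' @return list with `coefficients` (filtered) and `modules` (named list
#'   TF -> target vector).
#' @export
selectModules <- function(model, alpha = 0.05) {
  ok <- model$fits$target[!is.na(model$fits$padj) & model$fits$padj < alpha]
  cf <- model$coefficients[model$coefficients$target %in% ok, , drop = FALSE]
  modules <- split(cf$target, cf$tf)
  modules <- lapply(modules, unique)
  list(coefficients = cf, modules = modules)
}

#' Transcription-factor activity per time point
#'
#' Activity(TF, t) = mean model coefficient across the TF's retained
#' targets x mean normalized TF expression at time point t; TFs are
#' ranked per time point by highest positive activity. Activity is linear
#' in mean TF expression, and a TF unexpressed at a time point has
#' activity 0 there.
#'
#' @param model a `GrnModel`
#' @param expr genes x cells normalized expression (full cell set)
#' @param timepoints per-cell time point vector (names = barcodes)
#' @param modules optional output of [selectModules()]; default averages
#'   over all modeled targets
#' @return data.frame with `tf`, `timepoint`, `meanCoef`, `meanExpr`,
#'   `activity`, `rank` (1 = highest activity within the time point).
#' @export
tfActivity <- function(model, expr, timepoints, modules = NULL) {
  cf <- if (is.null(modules)) model$coefficients else modules$coefficients
  tfs <- unique(cf$tf)
  absent <- setdiff(tfs, rownames(expr))
  if (length(absent)) {
    warning("TF(s) absent from expression matrix: ",
            paste(absent, collapse = ", "))
    tfs <- setdiff(tfs, absent)
  }
  timepoints <- timepoints[colnames(expr)]
  tps <- intersect(stageLevels(), unique(timepoints))
  if (!length(tps)) tps <- unique(timepoints)
  meanCoef <- vapply(tfs, function(tf) mean(cf$estimate[cf$tf == tf]),
                     numeric(1))
  out <- NULL
  for (tp in tps) {
    cells <- names(timepoints)[timepoints == tp]
    me <- Matrix::rowMeans(expr[tfs, cells, drop = FALSE])
    act <- meanCoef * me
    out <- rbind(out, data.frame(tf = tfs, timepoint = tp,
                                 meanCoef = unname(meanCoef),
                                 meanExpr = unname(me),
                                 activity = unname(act),
                                 rank = rank(-act, ties.method = "first"),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
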