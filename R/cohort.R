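#' @importFrom stats predict dist
NULL

#' Train the chrX/chrY sex classifier
#'
#' Ridge-penalized logistic regression (via glmnet at a fixed small
#' penalty) on normalized expression of X- and Y-linked genes. Classes
#' are balanced by seeded downsampling before a train/holdout split;
#' accuracy, sensitivity (female recall) and specificity (male recall)
#' are computed on the holdout.
#'
#' @param norm genes x cells normalized expression
#' @param labels per-cell sex labels, `"F"`/`"M"` (names = barcodes)
#' @param xyGenes X/Y-linked feature genes present in `norm`
#' @param holdoutFraction fraction of balanced cells held out (default 0.3)
#' @param seed seed for balancing and splitting
#' @param lambda ridge penalty (default 0.01)
#' @return a `SexModel` list: `fit` (glmnet), `features`, `metrics`
#'   (accuracy, sensitivity, specificity), `holdoutCells`, `trainCells`.
#' @export
trainSexClassifier <- function(norm, labels, xyGenes,
                               holdoutFraction = 0.3, seed = 1L,
                               lambda = 0.01) {
  xyGenes <- intersect(xyGenes, rownames(norm))
  if (!length(xyGenes)) stop("no X/Y feature genes present")
  labels <- labels[colnames(norm)]
  classes <- unique(stats::na.omit(labels))
  if (length(classes) < 2) stop("both sexes must be present to train")
  set.seed(as.integer(seed))
  byClass <- split(names(labels), labels)
  nPer <- min(lengths(byClass))
  balanced <- unlist(lapply(byClass, function(cells) sample(cells, nPer)))
  hold <- sample(balanced, round(length(balanced) * holdoutFraction))
  train <- setdiff(balanced, hold)

  X <- t(as.matrix(norm[xyGenes, train, drop = FALSE]))
  y <- factor(labels[train], levels = c("M", "F"))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda)
  Xh <- t(as.matrix(norm[xyGenes, hold, drop = FALSE]))
  ph <- as.numeric(predict(fit, Xh, type = "response"))
  pred <- ifelse(ph > 0.5, "F", "M")
  truth <- labels[hold]
  metrics <- c(
    accuracy = mean(pred == truth),
    sensitivity = mean(pred[truth == "F"] == "F"),
    specificity = mean(pred[truth == "M"] == "M"))
  structure(list(fit = fit, features = xyGenes, metrics = metrics,
                 holdoutCells = hold, trainCells = train, lambda = lambda),
            class = "SexModel")
}

#' Predict per-cell sex
#'
#' Applies a trained [trainSexClassifier()] model to every cell. Cells
#' with no signal at any X/Y feature are labeled `"unassigned"`. When
#' a priori labels are supplied, disagreeing cells are flagged.
#'
#' @param model a `SexModel`
#' @param norm genes x cells normalized expression
#' @param knownLabels optional a priori per-cell sex labels to audit
#' @return data.frame with `cell`, `sex`, `score` (probability female)
#'   and, when `knownLabels` is given, `flagged` (predicted != known).
#' @export
predictSex <- function(model, norm, knownLabels = NULL) {
  X <- t(as.matrix(norm[model$features, , drop = FALSE]))
  p <- as.numeric(predict(model$fit, X, type = "response"))
  sex <- ifelse(p > 0.5, "F", "M")
  zero <- rowSums(abs(X)) == 0
  sex[zero] <- "unassigned"
  out <- data.frame(cell = colnames(norm), sex = sex, score = p,
                    stringsAsFactors = FALSE)
  if (!is.null(knownLabels)) {
    kn <- knownLabels[out$cell]
    out$flagged <- !is.na(kn) & sex != "unassigned" & sex != kn
  }
  out
}

## Perplexity-calibrated neighborhood probabilities for one cell:
## binary-search the Gaussian bandwidth so the entropy matches
## log(perplexity), as in SNE-style neighbor weighting.
.neighborProbs <- function(d2, perplexity, tol = 1e-5, maxIter = 64) {
  beta <- 1
  logU <- log(perplexity)
  lo <- -Inf; hi <- Inf
  for (it in seq_len(maxIter)) {
    w <- exp(-d2 * beta)
    sw <- sum(w)
    if (sw == 0) { beta <- beta / 10; next }
    H <- log(sw) + beta * sum(d2 * w) / sw
    diff <- H - logU
    if (abs(diff) < tol) break
    if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w <- exp(-d2 * beta)
  w / sum(w)
}

#' Local inverse Simpson's index of label mixing
#'
#' For each cell, neighbor weights over the `3 * perplexity` nearest
#' cells in the embedding are calibrated to the perplexity with a
#' Gaussian kernel; the inverse Simpson's index of the label distribution
#' under those weights gives the raw LISI in \[1, R\] (R = number of
#' labels), normalized to \[0, 1\] as (raw - 1) / (R - 1). Invariant to
#' label renaming and rigid motions of the embedding.
#'
#' @param embedding cells x 2 coordinate matrix (rownames = barcodes)
#' @param labels per-cell replicate labels (names = barcodes); at least
#'   two distinct labels are required
#' @param perplexity neighborhood size parameter (default 30)
#' @return list with `perCell` (data.frame cell, raw, normalized),
#'   `fractionAtLeastHalf` (share of cells with normalized LISI >= 0.5)
#'   and `nLabels`.
#' @export
lisiScore <- function(embedding, labels, perplexity = 30) {
  embedding <- as.matrix(embedding)
  if (!all(is.finite(embedding))) stop("embedding must be finite")
  labels <- labels[rownames(embedding)]
  R <- length(unique(labels))
  if (R < 2) stop("at least two labels required (R - 1 = 0 otherwise)")
  n <- nrow(embedding)
  k <- min(n - 1, max(as.integer(3 * perplexity), 10))
  perp <- min(perplexity, k - 1)
  labInt <- as.integer(factor(labels))
  D <- as.matrix(dist(embedding))^2
  raw <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])[-1][seq_len(k)]
    p <- .neighborProbs(D[i, ord], perp)
    pl <- vapply(seq_len(R), function(l) sum(p[labInt[ord] == l]), numeric(1))
    raw[i] <- 1 / sum(pl^2)
  }
  normalized <- pmin(pmax((raw - 1) / (R - 1), 0), 1)
  perCell <- data.frame(cell = rownames(embedding), raw = raw,
                        normalized = normalized, stringsAsFactors = FALSE)
  list(perCell = perCell,
       fractionAtLeastHalf = mean(normalized >= 0.5),
       nLabels = R)
}

#' Seeded equal-count downsampling per label
#'
#' Utility for mixing assessment on an equivalent number of cells per
#' replicate: keeps `min(table(labels))` cells of every label.
#'
#' @param labels per-cell labels (names = barcodes)
#' @param seed seed
#' @return character vector of retained barcodes.
#' @export
downsampleBalanced <- function(labels, seed = 1L) {
  set.seed(as.integer(seed))
  byLab <- split(names(labels), labels)
  nPer <- min(lengths(byLab))
  unlist(lapply(byLab, function(cells) sample(cells, nPer)), use.names = FALSE)
}
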