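#' @importFrom stats rnorm runif rbinom rnbinom rbeta qnbinom pnorm rlnorm
#'   setNames
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

## Splittable substreams: every generation stage reseeds from the global
## seed plus a fixed stage offset, so stages are individually reproducible.
.substream <- function(seed, k) {
  set.seed(as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647))
}

#' Simulation configuration for paired multiome data
#'
#' Defines the study conditions for [simulateMultiome()]: the sample sheet
#' (five disease stages with replicates), cell-type mixing, the planted
#' immune and damage programs, chromatin priming, DORC peak-gene blocks,
#' transcription-factor drivers and sex markers.
#'
#' The default per-stage immune fractions are the study's observed
#' immune-oligodendroglia percentages (26.80% early, 66.91% peak, 32.41%
#' late), with immune cells essentially absent from the two control arms.
#' `immuneEffectSize` shifts the per-cell program activity latent in units
#' of its baseline (control) standard deviation. Program genes load on the
#' shared latent with a log-scale loading of about 0.6, so the module-score
#' separation between planted and background cells is approximately
#' `immuneEffectSize` null-score standard deviations (the normalization's
#' log1p compression attenuates it mildly).
#'
#' @param nCellsPerSample cells per sample (positive integer)
#' @param samples data.frame with columns `sample`, `timepoint`
#'   (subset of [stageLevels()]) and `replicate`; default two replicates of
#'   each of the five stages
#' @param cellTypes named numeric of mixing proportions summing to 1
#' @param immuneFraction named numeric, per-timepoint fraction of cells
#'   carrying the immune program
#' @param damageFraction per-timepoint fraction with the damage program;
#'   default 0.6 x `immuneFraction`
#' @param immuneEffectSize shift of the immune/damage program activity
#'   latent, in baseline s.d. units
#' @param chromatinPriming logical; when TRUE a fraction of non-expressing
#'   cells (in every stage, including controls) carry open program peaks
#' @param primingFraction fraction of non-immune control-arm (naive/cfa)
#'   cells primed; priming is planted asymmetrically: disease-stage cells
#'   are primed at `primingFractionEae` instead, mirroring the
#'   already-primed control chromatin that raises the chromatin null
#' @param primingFractionEae priming fraction at disease stages
#' @param nGenes,nPeaks total feature counts (must accommodate the planted
#'   structures)
#' @param nProgramGenes,nDamageGenes sizes of the planted immune and damage
#'   expression programs
#' @param dorcGenes data.frame with columns `nLinkedPeaks` (peaks planted
#'   within 50 kb of the TSS) and `strength` (latent copula correlation in
#'   (0,1)); one simulated gene per row. Each DORC gene additionally gets
#'   two correlated far peaks at 150/300 kb to exercise the 500-kb window.
#' @param nTfs number of transcription-factor genes; the first is a
#'   stage-specific activator, the next three are weak constitutive
#'   activators, the rest are inert
#' @param nTfTargets targets of the stage-specific activator
#' @param tfActiveStage stage at which the planted activator is expressed
#' @param tfEffect log-scale effect of the activator product predictor on
#'   its targets
#' @param sexFractionFemale probability a cell is female
#' @param dispersion negative-binomial dispersion of counts
#' @param seed integer seed driving all substreams
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(nCellsPerSample = 200,
                      samples = NULL,
                      cellTypes = c(MOL2 = 0.4, MOL56 = 0.4, OPC = 0.2),
                      immuneFraction = c(naive = 0, cfa = 0,
                                         early = 0.268, peak = 0.6691,
                                         late = 0.3241),
                      damageFraction = NULL,
                      immuneEffectSize = 3,
                      chromatinPriming = TRUE,
                      primingFraction = 0.35, primingFractionEae = 0.05,
                      nGenes = 600, nPeaks = 1000,
                      nProgramGenes = 30, nDamageGenes = 20,
                      dorcGenes = data.frame(nLinkedPeaks = c(6, 6, 5, 4),
                                             strength = 0.6),
                      nTfs = 20, nTfTargets = 20,
                      tfActiveStage = "peak", tfEffect = 0.5,
                      sexFractionFemale = 0.5,
                      dispersion = 0.1,
                      seed = 1L) {
  if (is.null(samples)) {
    samples <- data.frame(
      sample = paste0(rep(stageLevels(), each = 2), "_r", 1:2),
      timepoint = rep(stageLevels(), each = 2),
      replicate = paste0("r", rep(1:2, times = 5)))
  }
  cfg <- list(nCellsPerSample = as.integer(nCellsPerSample),
              samples = samples, cellTypes = cellTypes,
              immuneFraction = immuneFraction,
              damageFraction = if (is.null(damageFraction))
                pmin(immuneFraction * 0.6, 1) else damageFraction,
              immuneEffectSize = immuneEffectSize,
              chromatinPriming = isTRUE(chromatinPriming),
              primingFraction = primingFraction,
              primingFractionEae = primingFractionEae,
              nGenes = as.integer(nGenes), nPeaks = as.integer(nPeaks),
              nProgramGenes = as.integer(nProgramGenes),
              nDamageGenes = as.integer(nDamageGenes),
              dorcGenes = dorcGenes,
              nTfs = as.integer(nTfs), nTfTargets = as.integer(nTfTargets),
              tfActiveStage = tfActiveStage, tfEffect = tfEffect,
              sexFractionFemale = sexFractionFemale,
              dispersion = dispersion, seed = as.integer(seed))
  validateSimConfig(cfg)
  class(cfg) <- "SimConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$nCellsPerSample <= 0) stop("nCellsPerSample must be positive")
  if (cfg$nGenes <= 0 || cfg$nPeaks <= 0) stop("nGenes and nPeaks must be positive")
  if (abs(sum(cfg$cellTypes) - 1) > 1e-9)
    stop("cellTypes proportions must sum to 1")
  tps <- unique(cfg$samples$timepoint)
  if (!all(tps %in% stageLevels()))
    stop("sample timepoints must be in stageLevels()")
  for (fr in list(cfg$immuneFraction, cfg$damageFraction)) {
    if (!all(tps %in% names(fr)))
      stop("immune/damage fractions must name every sampled timepoint")
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  }
  for (pf in c(cfg$primingFraction, cfg$primingFractionEae))
    if (pf < 0 || pf > 1) stop("priming fractions must lie in [0, 1]")
  if (cfg$sexFractionFemale < 0 || cfg$sexFractionFemale > 1)
    stop("sexFractionFemale must lie in [0, 1]")
  if (nrow(cfg$dorcGenes) > 0) {
    if (any(cfg$dorcGenes$nLinkedPeaks < 1)) stop("dorc nLinkedPeaks must be >= 1")
    if (any(cfg$dorcGenes$strength <= 0 | cfg$dorcGenes$strength >= 1))
      stop("dorc strength must lie in (0, 1)")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  nSpecial <- cfg$nProgramGenes + cfg$nDamageGenes + nrow(cfg$dorcGenes) +
    cfg$nTfs + cfg$nTfTargets + 6L
  if (cfg$nGenes < nSpecial)
    stop(sprintf("nGenes (%d) too small for planted structures (need >= %d)",
                 cfg$nGenes, nSpecial))
  invisible(TRUE)
}

## NB count via Gaussian copula quantile transform (preserves NB marginal,
## plants rank correlation through the shared latent z).
.copulaNB <- function(z, mu, size) {
  qnbinom(pmin(pnorm(z), 1 - 1e-12), size = size, mu = mu)
}

#' Simulate a paired single-cell RNA + ATAC dataset with ground truth
#'
#' Generates negative-binomial RNA and gated negative-binomial ATAC counts
#' over a synthetic two-chromosome (plus chrX/chrY) genome with: a planted
#' immune expression program present in a configurable fraction of cells
#' per disease stage, chromatin priming (program peaks open in a fraction
#' of non-expressing cells of every stage), a damage program, DORC genes
#' whose peaks are copula-correlated with their expression, a
#' stage-specific transcription-factor driver with motif-annotated target
#' peaks, and X/Y sex-marker genes. Identical seeds give identical output.
#'
#' @param config a [simConfig()] object
#' @return A list with elements `dataset` (a
#'   [MultiomeExperiment-class]) and `truth`, the exhaustive ground-truth
#'   ledger (per-cell flags; program, damage and sex genes; planted
#'   peak-gene links with strengths; TF drivers, targets and motif table).
#' @examples
#' sim <- simulateMultiome(simConfig(nCellsPerSample = 50, seed = 7))
#' table(cellData(sim$dataset)$timepoint, sim$truth$cells$immune)
#' @export
simulateMultiome <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  cfg <- config
  disp <- cfg$dispersion
  size <- 1 / disp
  sigLat <- sqrt(log(1 + disp))  # baseline latent log-scale s.d.

  ## ---- gene annotation -------------------------------------------------
  gn <- list(
    program = sprintf("Imm%02d", seq_len(cfg$nProgramGenes)),
    damage  = sprintf("Dmg%02d", seq_len(cfg$nDamageGenes)),
    dorc    = if (nrow(cfg$dorcGenes)) sprintf("Dorc%d", seq_len(nrow(cfg$dorcGenes))) else character(),
    tf      = sprintf("Tf%02d", seq_len(cfg$nTfs)),
    target  = sprintf("Tgt%02d", seq_len(cfg$nTfTargets)),
    sex     = c("XistL", "Uty", "Eif2s3y", "Ddx3y", "Kdm5d", "Usp9y"))
  nBg <- cfg$nGenes - length(unlist(gn))
  gn$background <- if (nBg > 0) sprintf("Bg%03d", seq_len(nBg)) else character()
  geneIds <- unlist(gn, use.names = FALSE)

  autosomal <- setdiff(geneIds, gn$sex)
  chrom <- rep(c("chr1", "chr2"), length.out = length(autosomal))
  idx1 <- chrom == "chr1"
  pos <- integer(length(autosomal))
  pos[idx1] <- 1e6 + 120000 * (seq_len(sum(idx1)) - 1)
  pos[!idx1] <- 1e6 + 120000 * (seq_len(sum(!idx1)) - 1)
  strand <- rep(c("+", "-"), length.out = length(autosomal))
  tss <- pos
  gstart <- ifelse(strand == "+", tss, tss - 10000L)
  gend <- gstart + 10000L
  sexChrom <- c("chrX", "chrY", "chrY", "chrY", "chrY", "chrY")
  sexTss <- c(1e6, 1e6, 2e6, 3e6, 4e6, 5e6)
  genes <- GRanges(
    seqnames = c(chrom, sexChrom),
    ranges = IRanges(start = c(gstart, sexTss),
                     end = c(gend, sexTss + 10000)),
    strand = c(strand, rep("+", 6)))
  names(genes) <- c(autosomal, gn$sex)
  genes$tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                      GenomicRanges::end(genes), GenomicRanges::start(genes))
  genes <- genes[geneIds]

  ## ---- cells -----------------------------------------------------------
  .substream(cfg$seed, 1)
  smp <- cfg$samples
  nCells <- cfg$nCellsPerSample * nrow(smp)
  cellSample <- rep(smp$sample, each = cfg$nCellsPerSample)
  cellTp <- rep(smp$timepoint, each = cfg$nCellsPerSample)
  cellRep <- rep(smp$replicate, each = cfg$nCellsPerSample)
  barcodes <- sprintf("cell%05d", seq_len(nCells))
  cellType <- sample(names(cfg$cellTypes), nCells, replace = TRUE,
                     prob = cfg$cellTypes)
  sex <- ifelse(runif(nCells) < cfg$sexFractionFemale, "F", "M")
  immune <- runif(nCells) < cfg$immuneFraction[cellTp]
  damage <- runif(nCells) < cfg$damageFraction[cellTp]
  primed <- rep(FALSE, nCells)
  if (cfg$chromatinPriming) {
    pFrac <- ifelse(cellTp %in% c("naive", "cfa"),
                    cfg$primingFraction, cfg$primingFractionEae)
    primed <- !immune & runif(nCells) < pFrac
  }

  ## ---- per-cell latents and size factors -------------------------------
  .substream(cfg$seed, 2)
  sampleOffset <- setNames(rnorm(nrow(smp), 0, 0.2), smp$sample)
  sfRna <- exp(rnorm(nCells, 0, 0.3) + sampleOffset[cellSample])
  sfAtac <- exp(rnorm(nCells, 0, 0.3) + 0.5 * sampleOffset[cellSample])
  ## Program activity latents: baseline N(0,1); flagged cells N(effect,
  ## 0.55^2): the planted population expresses the program coherently, so
  ## the effect is a clean separation in baseline s.d. units.
  aImm <- rnorm(nCells, 0, 1)
  aImm[immune] <- rnorm(sum(immune), cfg$immuneEffectSize, 0.55)
  aDmg <- rnorm(nCells, 0, 1)
  aDmg[damage] <- rnorm(sum(damage), cfg$immuneEffectSize, 0.55)
  uDorc <- matrix(rnorm(nCells * max(1, nrow(cfg$dorcGenes))), ncol = nCells)
  ## calibrate the copula latent correlation against the attenuation the
  ## NB quantile transform and library-size factors impose on count-scale
  ## Pearson correlations: probe the realized pair correlation on fixed
  ## auxiliary latents and rescale the latent weight toward the target
  .substream(cfg$seed, 8)
  uP <- rnorm(nCells); egP <- rnorm(nCells); epP <- rnorm(nCells)
  calibrateRho <- function(target, muG, muP) {
    rl <- target
    for (k in 1:3) {
      w <- sqrt(rl)
      zg <- w * uP + sqrt(1 - rl) * egP
      zp <- w * uP + sqrt(1 - rl) * epP
      obs <- suppressWarnings(cor(.copulaNB(zg, muG, size),
                                  .copulaNB(zp, muP, size)))
      if (!is.finite(obs) || obs <= 0.01) break
      rl <- min(0.98, max(0.02, rl * target / obs))
    }
    rl
  }

  ## ---- RNA -------------------------------------------------------------
  .substream(cfg$seed, 3)
  baseMu <- setNames(rlnorm(length(geneIds), log(2), 0.8), geneIds)
  baseMu[gn$program] <- 10
  baseMu[gn$damage] <- 10
  baseMu[gn$dorc] <- 5
  baseMu[gn$tf] <- 2
  baseMu[gn$target] <- 3
  baseMu["XistL"] <- 0.05
  baseMu[gn$sex[-1]] <- 0.02

  logMu <- matrix(log(baseMu), nrow = length(geneIds), ncol = nCells,
                  dimnames = list(geneIds, barcodes))
  ## program genes co-fluctuate through the activity latent with a
  ## substantial log-scale loading (coherent inflammatory program); the
  ## effect size shifts the latent by multiples of its baseline s.d. (1)
  loadImm <- 0.6 * runif(cfg$nProgramGenes, 0.9, 1.1)
  loadDmg <- 0.6 * runif(cfg$nDamageGenes, 0.9, 1.1)
  logMu[gn$program, ] <- logMu[gn$program, ] + outer(loadImm, aImm)
  logMu[gn$damage, ] <- logMu[gn$damage, ] + outer(loadDmg, aDmg)
  ## sex markers
  logMu["XistL", sex == "F"] <- log(8)
  for (g in gn$sex[-1]) logMu[g, sex == "M"] <- log(4)
  ## TF drivers: Tf01 expressed at the active stage only; Tf02-Tf04 weak
  ## constitutive activators; the rest inert.
  if (cfg$nTfs >= 1) {
    logMu["Tf01", ] <- log(0.2)
    logMu["Tf01", cellTp == cfg$tfActiveStage] <- log(6)
  }
  logMu <- sweep(logMu, 2, log(sfRna), "+")
  rna <- matrix(rnbinom(length(logMu), size = size, mu = exp(logMu)),
                nrow = nrow(logMu), dimnames = dimnames(logMu))

  ## DORC genes by copula against shared latents
  dorcRhoLat <- numeric(nrow(cfg$dorcGenes))
  if (nrow(cfg$dorcGenes)) {
    for (i in seq_len(nrow(cfg$dorcGenes))) {
      dorcRhoLat[i] <- calibrateRho(cfg$dorcGenes$strength[i],
                                    baseMu[gn$dorc[i]] * sfRna, 2 * sfAtac)
      rho <- dorcRhoLat[i]
      z <- sqrt(rho) * uDorc[i, ] + sqrt(1 - rho) * rnorm(nCells)
      rna[gn$dorc[i], ] <- .copulaNB(z, mu = baseMu[gn$dorc[i]] * sfRna,
                                     size = size)
    }
  }

  ## ---- peaks -----------------------------------------------------------
  .substream(cfg$seed, 4)
  peakList <- list()
  addPeaks <- function(lst, ids, chr, center, width = 400L) {
    st <- as.integer(unname(center) - width / 2)
    chr <- unname(chr)
    rbind(lst, data.frame(peak = ids, chrom = chr, start = st,
                          end = st + width, stringsAsFactors = FALSE))
  }
  pk <- data.frame(peak = character(), chrom = character(),
                   start = integer(), end = integer())
  gTss <- setNames(genes$tss, names(genes))
  gChr <- setNames(as.character(GenomicRanges::seqnames(genes)), names(genes))
  ## promoter/program peaks sit inside the gene body next to the TSS
  progPeaks <- sprintf("pkImm%02d", seq_len(cfg$nProgramGenes))
  dir <- ifelse(as.character(GenomicRanges::strand(genes[gn$program])) == "+", 1, -1)
  pk <- addPeaks(pk, progPeaks, gChr[gn$program], gTss[gn$program] + dir * 500)
  dmgPeaks <- sprintf("pkDmg%02d", seq_len(cfg$nDamageGenes))
  dirD <- ifelse(as.character(GenomicRanges::strand(genes[gn$damage])) == "+", 1, -1)
  pk <- addPeaks(pk, dmgPeaks, gChr[gn$damage], gTss[gn$damage] + dirD * 500)
  ## DORC peaks: nLinkedPeaks within +/-50 kb, plus two far peaks for the
  ## 500-kb expanded window
  nearOffsets <- c(-45000, -20000, -8000, 8000, 20000, 45000, -30000, 30000)
  dorcLinks <- data.frame()
  for (i in seq_len(nrow(cfg$dorcGenes))) {
    k <- cfg$dorcGenes$nLinkedPeaks[i]
    offs <- nearOffsets[seq_len(k)]
    ids <- sprintf("pkDorc%d_%d", i, seq_len(k))
    pk <- addPeaks(pk, ids, gChr[gn$dorc[i]], gTss[gn$dorc[i]] + offs)
    far <- sprintf("pkDorc%d_far%d", i, 1:2)
    pk <- addPeaks(pk, far, gChr[gn$dorc[i]],
                   gTss[gn$dorc[i]] + c(-300000, 150000))
    dorcLinks <- rbind(dorcLinks, data.frame(
      gene = gn$dorc[i], peak = c(ids, far),
      strength = cfg$dorcGenes$strength[i],
      window = c(rep("50kb", k), rep("500kb", 2))))
  }
  ## motif peaks near each TF target's TSS
  tgtPeaks <- sprintf("pkTgt%02d", seq_len(cfg$nTfTargets))
  dirT <- ifelse(as.character(GenomicRanges::strand(genes[gn$target])) == "+", 1, -1)
  pk <- addPeaks(pk, tgtPeaks, gChr[gn$target], gTss[gn$target] + dirT * 2000)
  ## decoy-activator target peaks sit next to their target genes' TSSs so
  ## the nearest-gene assignment recovers the planted pairs
  decoys <- if (cfg$nTfs >= 4) c("Tf02", "Tf03", "Tf04") else character()
  decoyPeaks <- character(); decoyTgtGenes <- character()
  if (length(decoys) && length(gn$background) >= 10 * length(decoys)) {
    decoyTgtGenes <- gn$background[seq_len(10 * length(decoys))]
    decoyPeaks <- sprintf("pkDec%02d", seq_along(decoyTgtGenes))
    dirB <- ifelse(as.character(GenomicRanges::strand(genes[decoyTgtGenes])) == "+", 1, -1)
    pk <- addPeaks(pk, decoyPeaks, gChr[decoyTgtGenes],
                   gTss[decoyTgtGenes] + dirB * 2000)
  }
  nBgPk <- cfg$nPeaks - nrow(pk)
  if (nBgPk < 0) stop("nPeaks too small for planted peak structures")
  if (nBgPk > 0) {
    bgChr <- rep(c("chr1", "chr2"), length.out = nBgPk)
    maxPos <- max(gTss[autosomal]) + 500000
    bgCenter <- round(runif(nBgPk, 50000, maxPos))
    pk <- addPeaks(pk, sprintf("pkBg%04d", seq_len(nBgPk)), bgChr, bgCenter)
  }
  peaks <- GRanges(pk$chrom, IRanges(pk$start + 1L, pk$end))  # stored 1-based
  names(peaks) <- pk$peak

  ## ---- ATAC ------------------------------------------------------------
  .substream(cfg$seed, 5)
  atac <- matrix(0L, nrow = length(peaks), ncol = nCells,
                 dimnames = list(names(peaks), barcodes))
  gateNB <- function(pOpen, mu) {
    as.integer(rbinom(nCells, 1, pOpen) *
               rnbinom(nCells, size = size, mu = mu * sfAtac))
  }
  ## open in expressing and primed cells; expressing cells carry somewhat
  ## more fragments per open peak than silently primed ones
  openProg <- ifelse(immune | primed, 0.9, 0.05)
  muProg <- ifelse(immune, 2.5, 2)
  for (p in progPeaks) atac[p, ] <- gateNB(openProg, muProg)
  openDmg <- ifelse(damage | primed, 0.9, 0.05)
  muDmg <- ifelse(damage, 2.5, 2)
  for (p in dmgPeaks) atac[p, ] <- gateNB(openDmg, muDmg)
  if (nrow(dorcLinks)) {
    for (i in seq_len(nrow(cfg$dorcGenes))) {
      rho <- dorcRhoLat[i]
      ids <- dorcLinks$peak[dorcLinks$gene == gn$dorc[i]]
      for (p in ids) {
        z <- sqrt(rho) * uDorc[i, ] + sqrt(1 - rho) * rnorm(nCells)
        atac[p, ] <- .copulaNB(z, mu = 2 * sfAtac, size = size)
      }
    }
  }
  for (p in tgtPeaks) atac[p, ] <- gateNB(0.7, 2)
  for (p in decoyPeaks) atac[p, ] <- gateNB(0.7, 2)
  bgIds <- grep("^pkBg", names(peaks), value = TRUE)
  if (length(bgIds)) {
    commonness <- runif(length(bgIds), 0.2, 0.9)
    for (j in seq_along(bgIds)) atac[bgIds[j], ] <- gateNB(commonness[j], 1.2)
  }

  ## ---- TF targets (need TF expression and motif-peak accessibility) ----
  .substream(cfg$seed, 6)
  motif <- data.frame()
  if (cfg$nTfs >= 1 && cfg$nTfTargets >= 1) {
    normTf <- log1p(rna["Tf01", ] / pmax(colSums(rna), 1) * 1e4)
    zTf <- as.numeric(scale(normTf))
    for (j in seq_len(cfg$nTfTargets)) {
      accN <- log1p(atac[tgtPeaks[j], ] / pmax(colSums(atac), 1) * 1e4)
      zAcc <- as.numeric(scale(accN))
      pred <- zTf * zAcc
      mu <- baseMu[gn$target[j]] * sfRna * exp(cfg$tfEffect * pred)
      rna[gn$target[j], ] <- rnbinom(nCells, size = size, mu = mu)
      extra <- if (cfg$nTfs > 4)
        sample(gn$tf[5:cfg$nTfs], min(2, cfg$nTfs - 4)) else character()
      motif <- rbind(motif, data.frame(peak = tgtPeaks[j],
                                       tf = c("Tf01", extra)))
    }
  }
  ## constitutive decoy activators Tf02..Tf04 driving background genes
  decoyTargets <- list()
  if (length(decoyTgtGenes)) {
    for (d in seq_along(decoys)) {
      tgts <- decoyTgtGenes[((d - 1) * 10 + 1):(d * 10)]
      pksd <- decoyPeaks[((d - 1) * 10 + 1):(d * 10)]
      zD <- as.numeric(scale(log1p(rna[decoys[d], ] / pmax(colSums(rna), 1) * 1e4)))
      for (j in seq_along(tgts)) {
        zA <- as.numeric(scale(log1p(atac[pksd[j], ] / pmax(colSums(atac), 1) * 1e4)))
        mu <- baseMu[tgts[j]] * sfRna * exp(0.4 * zD * zA)
        rna[tgts[j], ] <- rnbinom(nCells, size = size, mu = mu)
        motif <- rbind(motif, data.frame(peak = pksd[j], tf = decoys[d]))
      }
      decoyTargets[[decoys[d]]] <- tgts
    }
  }

  ## ---- FRiP / off-peak fragments, embedding ----------------------------
  .substream(cfg$seed, 7)
  sampleFrip <- setNames(runif(nrow(smp), 0.64, 0.79), smp$sample)
  fripCell <- rbeta(nCells, sampleFrip[cellSample] * 60,
                    (1 - sampleFrip[cellSample]) * 60)
  inPeak <- colSums(atac)
  offPeak <- as.integer(round(inPeak * (1 - fripCell) / fripCell))
  centers <- matrix(c(0, 0, 6, 0, 3, 6), ncol = 2, byrow = TRUE)
  rownames(centers) <- names(cfg$cellTypes)[seq_len(min(3, length(cfg$cellTypes)))]
  ci <- match(cellType, rownames(centers))
  ci[is.na(ci)] <- 1L
  emb <- centers[ci, , drop = FALSE] + matrix(rnorm(2 * nCells, 0, 1.2), ncol = 2)

  colData <- S4Vectors::DataFrame(
    sample = cellSample, replicate = cellRep, timepoint = cellTp,
    cell_type = cellType, sex = sex,
    total_fragments = inPeak + offPeak,
    umap_1 = emb[, 1], umap_2 = emb[, 2],
    row.names = barcodes)

  dataset <- MultiomeExperiment(rna = rna, atac = atac, genes = genes,
                                peaks = peaks, colData = colData)
  truth <- list(
    cells = data.frame(cell = barcodes, sample = cellSample,
                       timepoint = cellTp, cell_type = cellType,
                       immune = immune, damage = damage, primed = primed,
                       sex = sex, stringsAsFactors = FALSE),
    programGenes = gn$program,
    damageGenes = gn$damage,
    programPeaks = progPeaks,
    damagePeaks = dmgPeaks,
    dorcLinks = dorcLinks,
    dorcGenes = gn$dorc,
    sexGenes = list(x = "XistL", y = gn$sex[-1]),
    tf = list(driver = if (cfg$nTfs >= 1) "Tf01" else character(),
              activeStage = cfg$tfActiveStage,
              targets = gn$target, targetPeaks = tgtPeaks,
              decoys = decoyTargets),
    motifTable = motif,
    immuneFraction = cfg$immuneFraction,
    realizedImmuneFraction = vapply(
      split(immune, cellTp), mean, numeric(1)),
    seed = cfg$seed)
  list(dataset = dataset, truth = truth)
}

#' Simulate paired bulk RNA/ATAC tables for a two-dose stimulation design
#'
#' Emulates a 1x/2x cytokine stimulation experiment: four conditions
#' (control; first dose sampled at +0 h; first dose after a 96-h washout;
#' second dose). Planted "memory" genes are upregulated on the first dose
#' at the RNA level while their chromatin accessibility is elevated on dose
#' one and unchanged between +0 h and washout; half of them are further
#' upregulated on the second dose. All other genes are exchangeable across
#' conditions.
#'
#' @param nGenes total genes (each gene gets one 1-kb accessibility region)
#' @param nMemoryGenes planted memory genes (must be <= `nGenes`)
#' @param nReplicates replicates per condition (>= 2)
#' @param effectLog2fc RNA log2 fold change of memory genes on dose one
#' @param dispersion NB dispersion of both assays (bulk-scale default)
#' @param seed integer seed
#' @return list with `rna` and `atac` integer count matrices (columns
#'   `<condition>_r<replicate>` over conditions ctrl, d1, wash, d2),
#'   `condition`/`replicate` vectors, `regions` (a `GRanges`, one TSS
#'   region per gene) and `truth` (memory genes and the dose-2 boosted
#'   subset).
#' @export
simulateBulkMemory <- function(nGenes = 2000, nMemoryGenes = 100,
                               nReplicates = 3, effectLog2fc = 2,
                               dispersion = 0.01, seed = 1L) {
  if (nMemoryGenes > nGenes) stop("nMemoryGenes must be <= nGenes")
  if (nReplicates < 2) stop("at least 2 replicates required (dispersion not estimable)")
  .substream(seed, 11)
  conds <- c("ctrl", "d1", "wash", "d2")
  cond <- rep(conds, each = nReplicates)
  repl <- rep(paste0("r", seq_len(nReplicates)), times = length(conds))
  samples <- paste0(cond, "_", repl)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  memory <- genes[seq_len(nMemoryGenes)]
  boosted <- memory[seq_len(floor(nMemoryGenes / 2))]

  baseRna <- rlnorm(nGenes, log(100), 1)
  baseAtac <- rlnorm(nGenes, log(100), 0.6)
  libs <- exp(rnorm(length(samples), 0, 0.15))
  size <- 1 / dispersion

  fcRna <- matrix(1, nGenes, length(conds), dimnames = list(genes, conds))
  fcAtac <- matrix(1, nGenes, length(conds), dimnames = list(genes, conds))
  fcRna[memory, "d1"] <- 2^effectLog2fc
  fcRna[memory, "d2"] <- 2^effectLog2fc
  fcRna[boosted, "d2"] <- 2^(effectLog2fc + 1)
  ## weakly re-induced (non-boosted) memory genes: mild dose-2 increment
  weak <- setdiff(memory, boosted)
  fcRna[weak, "d2"] <- 2^(effectLog2fc + 0.4)
  ## chromatin opens on dose one and STAYS open through washout
  fcAtac[memory, c("d1", "wash", "d2")] <- 2

  rna <- matrix(0L, nGenes, length(samples), dimnames = list(genes, samples))
  atac <- matrix(0L, nGenes, length(samples), dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    rna[, j] <- rnbinom(nGenes, size = size,
                        mu = baseRna * fcRna[, cond[j]] * libs[j])
    atac[, j] <- rnbinom(nGenes, size = size,
                         mu = baseAtac * fcAtac[, cond[j]] * libs[j])
  }
  tssPos <- 1e6 + 5000 * (seq_len(nGenes) - 1)
  regions <- GRanges(rep(c("chr1", "chr2"), length.out = nGenes),
                     IRanges(tssPos - 499, tssPos + 500))
  names(regions) <- genes
  regions$gene <- genes
  list(rna = rna, atac = atac, condition = cond, replicate = repl,
       regions = regions,
       truth = list(memoryGenes = memory, boostedGenes = boosted,
                    seed = seed))
}
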