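# olgstate

Analysis toolkit for paired single-cell RNA + ATAC (multiome) studies of
oligodendroglia (OLG) state transitions during neuroinflammation, modeled on
the experimental autoimmune encephalomyelitis (EAE) time course: two control
arms (naive and adjuvant-only) followed by early, peak and late disease
stages. The package implements the computational procedures such a study
needs end to end, together with a synthetic paired-multiome generator that
plants every structure the procedures are meant to detect, so each stage can
be validated by parameter recovery against a ground-truth ledger.

## What it computes

**Immune / damage status per cell (the core statistic).** A gene-set module
score — the mean normalized expression of a signature minus the mean of
expression-matched control genes drawn from average-expression bins — is
min–max scaled to [0, 1] and referred to a Gaussian null fitted on control
cells (mean μ, sample s.d. σ):

```
F(x) = 1/2 [ 1 + erf( (x − μ) / (σ √2) ) ]
```

A cell is called *immune* (or *damage-associated*) when its upper-tail
probability P = 1 − F(x) falls below α = 0.05. Running the same machinery on
the gene-activity matrix (peak counts summed over the gene body plus 500 bp
upstream of the TSS, log-normalized) gives a chromatin-level status, and
`jointStatus()` combines damage and interferon calls into the four-way
both / ifn_only / damage_only / neither partition.

**Regulatory linking.** `linkPeaks()` ties peaks to genes by positive Pearson
correlation between normalized accessibility and expression (two-sided
t-test, df = n − 2; peak center within 50 kb of the TSS, detected in ≥ 10
cells, p < 0.05). Genes with ≥ 5 linked peaks are *domains of regulatory
chromatin* (DORCs); they are re-linked at 500 kb and scored per cell as
fragments in linked peaks over all in-peak fragments × 10,000.

**Pseudobulk differential testing.** Counts are summed per sample × cell
type (features with < 10 counts dropped; samples with < 5 cells and time
points with < 30 cells removed), then tested with DESeq2 (size factors,
dispersion shrinkage, Wald tests, Benjamini–Hochberg) over the four
disease-course contrasts early/control, peak/early, late/early, peak/late.
Features pass at |log2FC| > 1, adjusted p < 0.01, baseMean > 1, and are
classified into temporal Types 1–4 (control/early/peak/late-high) from their
0–1-scaled stage profiles.

**GRN and TF activity.** Per target gene, OLS of normalized expression on
products of TF expression × accessibility of motif-bearing candidate regions
assigned to the nearest TSS (≤ 2,000 cells per time point). TF activity at a
time point is the mean model coefficient across the TF's retained targets ×
the TF's mean expression there, ranked per time point.

**Cohort QC.** A ridge-logistic sex classifier on chrX/chrY markers
(Xist-like plus Uty/Eif2s3y/Ddx3y/Kdm5d-like genes) with balanced
train/holdout evaluation, and a perplexity-calibrated local inverse
Simpson's index (LISI) of replicate mixing on a 2-D embedding, normalized
from [1, R] to [0, 1].

**Bulk stimulation memory.** Nonoverlapping 1-kb TSS windows (TSS ± 25 bp,
strand-aware merge, recenter to 1 kb, final merge) and cCRE-derived enhancer
regions; fragment counting; edgeR TMM + NB GLM likelihood-ratio tests; and
the epigenetic-memory gate: a gene is a memory gene when it is upregulated
on a first stimulus (RNA p < 0.05 and FDR < 0.05) while its chromatin
accessibility is unchanged between the stimulated and washed-out states
(|logFC| < 0.5 and FDR > 0.05).

## Worked example

```r
library(olgstate)

sim <- simulateMultiome(simConfig(nCellsPerSample = 400, seed = 1))
d <- sim$dataset
d
#> class: MultiomeExperiment
#> rna: 600 genes x 4000 cells
#> atac: 1000 peaks x 4000 cells
#> colData columns: sample, replicate, timepoint, cell_type, sex, total_fragments, umap_1, umap_2
#> timepoints: naive=800 cfa=800 early=800 peak=800 late=800

cd <- cellData(d)
ctrl <- rownames(cd)[cd$timepoint == "naive"]
norm <- logNormalize(rnaCounts(d))
status <- scoreStatus(norm, sim$truth$programGenes, ctrl, seed = 1)
round(100 * tapply(status$status == "immune", as.character(cd$timepoint), mean), 1)
#>   cfa early  late naive  peak
#>   4.1  29.4  33.8   4.9  63.5
```

The naive/adjuvant arms sit at the nominal 5% false-positive rate while the
planted per-stage immune fractions (26.8% / 66.9% / 32.4%, realized with
binomial noise at 800 cells per stage) are recovered at the disease stages.
DORC discovery on the same dataset finds exactly the genes planted with at
least five correlated peaks:

```r
tfn <- tfidfNormalize(atacCounts(d))
links <- linkPeaks(norm, tfn, peakRanges(d), geneRanges(d), padjMax = 0.05)
dorcs <- defineDorcs(links, norm, tfn, peakRanges(d), geneRanges(d),
                     atacCounts(d), padjMax = 0.05)
subset(dorcs$genes, dorc)
#>     gene nLinks50 dorc
#> 24 Dorc1        6 TRUE
#> 25 Dorc2        6 TRUE
#> 26 Dorc3        5 TRUE
```

(The fourth simulated gene carries only four linked peaks and is correctly
left out.)

## Documentation

The methods vignette (`vignettes/olgstate-methods.Rmd`) describes the
statistical models, the synthetic-data design and its calibration, numerical
conventions and known limitations.
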