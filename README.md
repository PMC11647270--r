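# spotbench

Benchmarking differential gene expression (DEG) detection in spot-based
spatial transcriptomics (ST), with a simulated ground truth and a prior-based
gene selection scheme.

## The problem

Spot-based ST platforms (10x Visium and kin) capture transcripts at fixed
array positions, each covering anywhere from a few to hundreds of cells.
Three properties set the data apart from scRNA-seq: **spot heterogeneity**
(several cell types mix their transcripts in one spot), **transcript
leakage** (diffusion into neighbouring positions, including cell-free
background), and **severe sparsity** (shallow effective depth per spot).
DEG analysis between two tissue regions or conditions is still routinely run
with tools built for bulk or single-cell data, and there is no real-world
gold standard to say how well that works.

`spotbench` builds that gold standard *in silico* and uses it two ways:

1. **Benchmark**: a two-condition single-cell simulator with a validated DEG
   answer key feeds a Visium-like tissue assembler; leakage and downsampling
   are layered on to produce the stages `ST-M` (mixing only), `ST-L`
   (+leakage), `ST-D` (+downsampling) and `ST-LD` (both — the realistic
   case). Native DEG tests are scored per cell type with sensitivity,
   specificity, precision and F1.
2. **Method**: a *gene–cell specificity* selection scheme. For gene *g* and
   cell type *c<sub>i</sub>*,

   mean specificity(c_i, g) = counts(c_i, g) / Σ_j counts(c_j, g)

   where `counts(c, g)` is the average expression of *g* in type *c* (a
   `frequency` variant uses detection rates instead). Scores are learned
   from a single-cell prior, each gene is attributed to its argmax type,
   genes with max score ≥ τ are selected, and Benjamini–Hochberg FDR
   correction is applied with *m* equal to the number of selected genes
   only. Testing is done region-vs-region (no per-spot composition needed),
   which makes the scheme usable upstream of any DEG algorithm.

## Worked example

Simulate a tissue, check the ground truth, and compare single-cell analysis
with the realistic spatial configuration:

```r
library(spotbench)
cfg <- simConfig(n_genes = 500, n_cell_types = 4, p_de = 0.1,
                 n_spots = 400, array_rows = 40, array_cols = 40,
                 n_cells_per_type = 1500)
res <- runExperiment(cfg, stages = c("SC", "ST-M", "ST-LD"),
                     methods = "ttest", n_replicates = 2, seed = 1)
summariseExperiment(res, baseline_stage = "ST-LD")
#>  stage method     F1 sensitivity specificity delta_F1
#>     SC  ttest 0.9517       0.915       0.999    0.901
#>  ST-LD  ttest 0.0509       0.030       0.996    0.000
#>   ST-M  ttest 0.2404       0.268       0.956    0.190
```

The same Welch t-test that recovers nearly every true DEG on single cells
(F1 0.95) collapses on realistic spot data (F1 0.05); mixing alone already
accounts for most of the damage (ST-M at 0.24). The ground-truth QC that
gates every simulation prints as:

```r
tissue <- buildTissue(makeSCPrior(500, 4, seed = 1), cfg, seed = 1)
tissue$qc
#> QCReport: PASSED
#>   1. unanalyzable fraction     0.0000  [ok]
#>   2. max mean log2FC deviation 0.0326  [ok]  (64 per-gene violations)
#>   3. DEG fraction error        0.0075  [ok]
#>   4. top-100 congruence        0.9900  [ok]
```

Prior-based selection then trades gene coverage for reliability on the
ST-LD data (regional testing, subset-restricted BH):

```r
scores <- meanSpecificity(priorMeans(makeSCPrior(500, 4, seed = 1)))
# regional p-values on filtered ST-LD + selectGenes(scores, tau) +
# priorSelectedDEG(p, selection) give, per threshold tau:
#> threshold 0.3: 100 genes kept,  4 DEG calls, mean F1 = 0.500
#> threshold 0.5:  92 genes kept,  4 DEG calls, mean F1 = 0.500
#> threshold 0.7:  57 genes kept,  3 DEG calls, mean F1 = 0.500
```

against a mean F1 of ~0.05 when testing all genes, and ~3× the F1 of a
size-matched random gene selection (see the acceptance report below). The
F1 here is relative to the selected subset, the price being the true DEGs
that sit outside it.

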