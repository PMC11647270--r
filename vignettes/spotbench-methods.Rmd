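---
title: "spotbench: simulation models, quality control and the specificity selection scheme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotbench methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative models,
the quality-control criteria gating them, the artifact models, the native DEG
tests, the evaluation and the prior-based gene selection scheme — together
with the numerical choices made where the design was genuinely open.

## 1. The single-cell simulator

Counts for gene $g$ in a cell of type $c$ under condition $A$ are negative
binomial,

$$X_{g} \sim \mathrm{NB}\!\left(\mu_{gc},\ \phi_g\right),
\qquad \mathrm{Var}(X_g) = \mu_{gc} + \mu_{gc}^2/\phi_g,$$

with means $\mu_{gc}$ and dispersions $\phi_g$ taken from an `SCReference`
prior. Per cell type, a fraction `p_de` of genes is flagged differentially
expressed with log2 fold change $\pm$`logfc_magnitude` (sign fair-coin per
gene, so up- and down-regulation are balanced in expectation); condition $B$
uses $\mu_{gc}\cdot 2^{\mathrm{logFC}}$. The `GroundTruth` object stores the
flags, fold changes and both mean surfaces, and enforces
$\mu_B = \mu_A 2^{\mathrm{logFC}}$ exactly.

The prior can be **estimated** from an annotated count matrix
(`estimatePrior()`) with the reference filters applied in order: cell types
need at least 50 cells per donor; cells need at least 500 total counts and
under 12% mitochondrial counts; genes need more than one count in at least
10 cells; and genes under the low-mean cutoff are removed. That cutoff is
not fixed by any external constraint — we default it to 0.005 counts/cell
(`low_mean_cutoff`) on the rationale that the simulator cannot reproduce
such means faithfully, so the empirical fold change of any DEG at that
expression would drift arbitrarily far from its parameterized value.
Dispersions are method-of-moments, $\hat\phi_g = \sum_t n_t \bar
x_{gt}^2 \,/\, \sum_t n_t (s^2_{gt} - \bar x_{gt})$, clamped to
$[10^{-3}, 10^8]$; a non-positive denominator (under-dispersion) maps to the
Poisson-limit cap.

Alternatively, `makeSCPrior()` draws a **synthetic prior**: baseline means
log-normal with meanlog $\ln 0.5$ and sdlog $1.2$ (sparse, overdispersed
counts in the dynamic range of droplet data), dispersions
$\Gamma(\text{shape}=2,\text{scale}=1)$, and a `marker_fraction` (default
0.2) of genes made type-restricted by multiplying their mean in one type by
a log-normal fold centred on `marker_fold = 8` with sdlog 0.8. The spread on
the fold matters: real markers vary in strength, and a single fixed fold
would make the specificity-score distribution bimodal, collapsing every
threshold between the two modes onto the same gene set.

What the generator does **not** emulate: donor or batch structure (the
reference is pooled deliberately, trading realism for lower variance),
gene–gene correlation, compositional library-size effects, multi-condition
designs, or cell states within a type. Passing tests therefore demonstrate
correctness of the pipeline's own contracts and the qualitative behaviour of
DEG methods under mixing/leakage/sparsity — not performance on any
particular real tissue.

## 2. Ground-truth quality control

A simulation is usable as a benchmark only if the realized counts honour the
recorded answer key. `qcGroundTruth()` checks four criteria; the dataset
passes only if all four hold. Criteria 2–4 are restricted to (gene, type)
pairs with positive empirical means in both conditions.

1. **Unanalyzable fraction ≤ 5%.** Pairs whose empirical means are zero in
   both conditions cannot be checked at all.
2. **Fold-change fidelity, 0.1 log2 tolerance.** We apply the tolerance to
   the *mean* empirical log2FC of the parameterized DEGs within each (cell
   type × direction) group. A per-gene reading of the same tolerance is not
   a fidelity measure: the sampling SE of a single gene's empirical log2FC
   at realistic depths is 0.07–0.3 (it is bounded below by
   $\sqrt{2\,/(\ln^2 2\cdot\phi n)}$ even for highly expressed genes), so
   individual violations occur with high probability for a *perfectly*
   faithful simulator. The per-gene violation count is still reported for
   diagnosis.
3. **Detected DEG fraction within 2 percentage points.** Genes are called
   empirically DE by a per-gene Welch t-test at $p < .01$; the detected
   fraction must sit within 0.02 of the parameterized fraction `p_de`. The
   comparison is on the percentage scale because a ratio to the
   parameterized *count* is structurally broken: the t-test's false
   positives alone contribute $\approx 0.01\,(1-p_{de})/p_{de}$ relative
   error (9% at `p_de` = 0.1) at any sample size.
4. **Top-100 congruence ≥ 60%.** Among the 100 pairs with the largest
   empirical |log2FC|, at least 60% must be parameterized DEGs.

## 3. Tissue assembly

Spots live on a pseudo-hex array in the doubled-column Visium convention:
position $(r, c)$ is valid when $r$ and $c$ share parity; the six neighbours
of a spot are $(r, c\pm2)$ and $(r\pm1, c\pm1)$. Euclidean coordinates in
spot units are $x = c/2$, $y = r\sqrt3/2$, so nearest neighbours sit at
distance 1. The array defaults to 78 × 64 (a standard capture area); all
placement happens inside it.

`placeSpots()` seeds one uniform-random spot, then proposes each next
position by independent steps of 0, ±1 or ±2 per axis from the current one.
Proposals that are off-array, off-parity or occupied restart the walk from a
random occupied spot; 1000 failed trials for one spot abort with its index.
The resulting tissues are contiguous blobs with occasional satellites — on
average over 90% of spots share one connected component.

`assignConditions()` splits the tissue into two mutually exclusive
condition regions (every cell in a spot shares the spot's condition, as in
disease tissue with adjacent healthy segments). The mechanism is our
choice: a random line through the centroid splits spots at the median
projection (sizes differ by at most one), then a repair loop flips
label-components disconnected from their label's main component and restores
balance by flipping boundary spots of the larger label. Within the tissue's
main component each region ends contiguous; satellite islands keep whatever
label repair leaves them.

`allocateCells()` draws, per cell type, a **uniformity state** (uniform
with probability `uniformity_prob`, else sparse: eligible spots are a random
subset of size `max(3, 2%)` of the region) and a **density state** (high
with probability `density_high_prob`; rates default to 4 and 0.5
cells/spot — the low end of what a capture spot holds, appropriate for
tissues with large cells). Each eligible spot receives
Poisson(rate) cells sampled *without replacement* from the matching
(type, condition) pool; reusing cells would correlate spots, so if a pool
runs short, `buildTissue()` re-simulates with twice as many cells rather
than recycling. `aggregateCounts()` then sums each spot's cells into the
`ST-M` dataset; background positions carry zero counts and composition.

## 4. Artifact models

**Leakage** (`applyLeakage()`): for each (spot, gene) the outflow is
Poisson(`bleed_rate` × count), capped at the available count; leaked
transcripts choose destinations by multinomial sampling over all array
positions (background included) with Gaussian-kernel weights
$w(s\to t) \propto \exp(-d_{st}^2 / 2\sigma^2)$, self-weight excluded, rows
normalized. When the cap was triggered for a gene, that gene's destinations
are re-sampled with probability proportional to
$\max(\text{received} - \overline{\text{received}}, 0)$ — the correction
rule is stated per spot in the underlying diffusion model and is ambiguous
about scope; we implement it per gene and log when it fires, taking "the
leakage distribution mean" as the mean received count over receiving spots.
Totals are conserved exactly by construction, and `bleed_rate = 0` is the
identity. Defaults `bleed_rate = 0.3`, `kernel_sd = 2` spot units are user
inputs (in the original setting they would be inferred from a separate ST
reference; that inverse problem is out of scope here).

**Downsampling** (`downsampleSpots()`): per spot, the retained total is
Normal(pct × total, `sd_frac` × pct × total) — `sd_frac` defaults to 0.1,
our choice where no value is prescribed — rounded and clipped to
[0, total]; genes are drawn multinomially at their original proportions, or
without replacement (multivariate hypergeometric) when `accurate = TRUE`,
which guarantees no (gene, spot) count exceeds its original.
`selectDownsamplePct()` picks the depth among candidates (default 10%, 7%,
5%, 3%, 2%, 1%, 0.5%) minimizing the sum of two-sample Kolmogorov–Smirnov
statistics of per-gene totals and per-gene means against a reference; ties
break toward the larger depth (retain more data when indifferent). The
fixed pipeline order is leak-then-downsample for `ST-LD`.

## 5. DEG testing and evaluation

`filterDataset()` drops genes with fewer than 3 counts, spots without
allocated cells (leak-only background) or without counts, then re-drops
empty genes. `normalizeLoglib()` implements
$\log(\text{count}/\text{total}\cdot 10^4 + 1)$; raw counts are the default
test input because normalization has little practical effect on the outcome
here — the switch is `deg$use_loglib`.

Spot groups come in three input modes: `containing` (≥1 cell of the focal
type; the standard per-type mode), `single` (strict majority composition,
mimicking spot annotation), and `regional` (whole condition regions,
identical for every cell type — obtainable in practice without any
composition knowledge). Tests: a vectorized Welch t-test (the common
"default t-test"; Welch rather than pooled, logged so users can compare), a
Wilcoxon rank-sum test (exact for group sizes ≤ 25 without ties, otherwise
the tie-corrected normal approximation), and an interaction model
`expr ~ condition + ratio + condition:ratio` over all spots, where `ratio`
is the (ground-truth) composition fraction of the focal type — the design
used to fold deconvolution output into a classic test; the two-sided
interaction p is reported and rank-deficient designs are flagged with
p = 1. Any test failure follows the NA rule: the p-value becomes 1.
`majorityVote()` calls a gene when at least ⌊m/2⌋+1 methods do.

Significance throughout is BH-adjusted p ≤ `alpha` with `alpha = 0.01`. The
evaluation definition conflates two readings ("p ≤ .01 divided by the
number of tested hypotheses" under a BH correction); we implement
BH-adjusted p ≤ .01, the standard FDR practice, and keep `alpha`
configurable so a Bonferroni-style `.01/m` can be emulated by passing that
value.

Scoring is pure confusion-table arithmetic per (method, cell type):
sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), F1 the
harmonic mean of precision and sensitivity; degenerate denominators score 0
with a flag. Untested genes count as non-calls but keep their ground truth
(they can only cost FN/TN). Subset analyses score relative to the subset.
The SC baseline subsamples the simulated cell pool to about 5000 cells so
single-cell and spatial analyses face comparable cell numbers.

## 6. The specificity selection scheme

Scores are row-normalized shares: per gene, the type means (metric
`"mean"`) or detection rates (`"frequency"`) divided by their sum across
types, so scores lie in [0, 1] and each scored gene's row sums to 1. Genes
with a zero denominator are unscored and can never be selected. Type means
are computed on raw per-cell counts (depth normalization before averaging is
switchable but off by default; the definition does not prescribe it, and on
QC-filtered cells the difference is minor). Attribution is argmax with ties
broken toward the lexicographically smallest type id — deterministic and
reproducible; each gene is evaluated for one cell type only, if at all.

Selection happens *after* the regional DEG test and affects only the FDR
correction: BH runs with m = #selected genes. Thresholds are inclusive
(≥ τ). Two matched baselines keep comparisons honest: `random` draws the
same number of genes uniformly; `external_list` draws from a supplied list
without repetition, reusing the whole list with repeats when more genes are
requested than it holds.

One caution from the mathematics of BH: restricting the gene set lowers
adjusted p-values when the removed genes have *larger* raw p than the
survivors, but removing a gene with smaller raw p can raise a survivor's
adjusted value. Subset selection is therefore a bet that the selected genes
concentrate the true signal — which is exactly what the specificity prior is
for — not a uniform monotonicity guarantee.

## 7. Determinism and problem sizes

Every stochastic stage draws its seed from `stageSeed(seed, stage)`, so the
same configuration and seed reproduce byte-identical datasets while stages
remain re-runnable in isolation. The test suite and `scripts/acceptance.R`
run everything at desk scale, the package's own choice of study conditions:
tissues of 100–400 spots on 20×20 to 40×40 arrays, 200–800 genes, 3–5 cell
types, 400–2000 cells per type and condition, three to five replicate
simulations, and 5% downsampling (the midpoint of the candidate grid, also
used as the self-recovery target in the KS calibration checks). Monte-Carlo
assertions state their tolerance as multiples of the analytic or empirical
standard error of the quantity under test.

## 8. Known limitations

- A gene is attributed to a single cell type; DE occurring in several types
  at once is invisible to the selection scheme by design.
- Exactly two conditions, mutually exclusive in space.
- Leakage and downsampling parameters are inputs, not inferred from real ST
  data; no decontamination (the inverse problem) is attempted.
- The NB simulator is per-gene independent; statistics that exploit
  gene–gene correlation will look better here than on real data.
- External DEG engines and deconvolution methods are not reimplemented;
  the results tables are method-tagged so their calls can be merged and
  scored by the same evaluation functions.
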