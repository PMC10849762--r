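# invadeR

Glioblastoma (GBM) owes its lethality to tumor cells that invade the
surrounding brain, and the metabolic rewiring that fuels those invasive
cells is hard to study because it requires separating the invasive
front from the tumor core and then pushing several very different data
types through consistent, reproducible analyses. invadeR is an R
package for exactly that workflow. It is written for computational
biologists analyzing invasion experiments in which the core and the
invasive fraction of the same tumor (a 3D hydrogel invasion device, a
site-directed biopsy pair, a xenograft section) are measured by pooled
CRISPR screening, microscopy, or metabolite/lipid/transcript profiling.

## What it computes

**Pooled CRISPR screen scoring.** Replicate sgRNA counts are summed per
fraction and scaled to counts per million; each guide gets a fitness

```
f_i = log2( (CPM_inv_i + c) / (CPM_core_i + c) ) - median_NT(f_raw)
```

with pseudocount `c = 0.5` CPM, referenced to the nontargeting (NT)
controls so the centered NT median is exactly 0. The gene score is the
median of its guides' fitness values (negative = depleted at the
invasive front = invasion-essential candidate), a two-sided one-sample
t test assesses deviation from 0, and hits are called at
`score <= -1, p <= 0.05` (symmetric for invasive-enriched). Per-sample
PCA of log2 CPM profiles checks that fractions separate.

**Invasion imaging.** From calibrated masks: invasion index
`(Af - Ai)/Ai`, control normalization, 8-connected cell segmentation
with centroid/area/perimeter/aspect-ratio/form-factor
(`4*pi*A/P^2`), detached cells (no neighbor within 10 µm), highly
invasive cells (centroid > 200 µm past the channel edge), and
elongated/round classes (aspect ratio >= 2).

**Fractal invasiveness.** Box-counting fractal dimension of a tumor
mask: `D` is the slope of `log N(s)` vs `log(1/s)`, with `N(s)` the
minimum number of occupied `s x s` boxes over a reflection-closed set
of grid offsets; boundary mode scores a planar tumor outline between 1
(smooth) and 2 (plane-filling), higher = more invasive.
`compare_invasiveness()` contrasts two groups of per-animal dimensions.

**Paired omics.** Per-feature fold change (invasive/core ratio of group
means over paired units), paired t tests on log2 abundances,
Benjamini–Hochberg adjustment, top-k ranking, median-of-ratios
(geometric-mean reference) normalization, hypergeometric
over-representation against GMT sets, fold-change concordance
(Pearson r and % sign-discordant features), and metabolic-catalog
subsetting.

**Synthetic data.** Seeded generators emulate every input — a
negative-binomial screen with planted invasion-essential genes,
log-normal paired abundance matrices with truly changed features, and
masks from analytic shapes (disk, line, Sierpinski carpet) to spheroid
fields, channel devices, and branched tumors — returning ground-truth
labels separately from the data so recovery can be tested honestly.

## Worked example

```r
library(invadeR)

sim <- simulate_screen_counts(screen_sim_config(
  n_genes = 200, guides_per_gene = 10, n_nontargeting = 100,
  frac_essential = 0.05, effect_log2 = -2, mean_depth = 500, seed = 7))
fit <- score_screen(sim)
summary(fit, n = 5)
#> Pooled CRISPR screen: 2100 guides, 200 genes scored
#> Hits at |log2FC| >= 1, p <= 0.05: 10 core-enriched, 0 invasive-enriched
#>
#> Top hits (sorted by p, then |score|):
#>       gene score  p_value n_guides     direction
#>  gene_0042 -1.92 2.09e-09       10 core_enriched
#>  gene_0103 -1.75 4.88e-08       10 core_enriched
#>  gene_0067 -2.12 4.89e-08       10 core_enriched
#>  gene_0136 -2.01 6.94e-08       10 core_enriched
#>  gene_0118 -2.00 9.72e-08       10 core_enriched

recovery_auroc(fit$genes, sim$truth)
#> [1] 1
```

All 10 planted essential genes are called as core-enriched hits and the
score ranking separates them perfectly from the 190 neutral genes
(AUROC 1 at this depth and effect size). On a simulated xenograft
section:

```r
tumor <- simulate_mask("branched_growth", image_size = 256,
                       branching_intensity = 3, seed = 5)
fractal_dimension(tumor)
#> Box-counting fractal dimension (boundary mode): D = 1.2355 (R^2 = 0.9945)
#>   6 scales: 2, 4, 8, 16, 32, 64 px
```

A branched, infiltrative growth pattern scores well above a smooth
disk's boundary dimension of 1. The whole chain — simulate, screen,
image rules, fractal, omics, with a JSON manifest and bit-identical
reruns — is driven by `run_pipeline()` or the CLI wrapper
`inst/scripts/invasion-pipeline.R`.

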