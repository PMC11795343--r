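# dustinct

Statistical distinctness testing for varieties of outbreeding crops, from
bulked-sample (pool-seq) SNP allele frequencies and from UPOV-style
spaced-plant trial data.

## The problem

Varieties of outbred forage crops such as alfalfa (*Medicago sativa*) are
synthetic populations: individual plants are genetically heterogeneous, so a
cultivar is characterized by its allele frequencies rather than a genotype.
Registration requires *distinctness* — the candidate must be statistically
distinguishable from every registered variety. Morphophysiological DUS
trials often fail to separate closely related cultivars; molecular
distinctness from pooled (bulked) DNA samples is the emerging alternative.
`dustinct` implements a complete multi-criterion framework for this
decision, plus a synthetic-data generator so every stage can be exercised
and calibrated without real data:

- **Marker filtering** — per-cell read-depth masking, per-marker
  missing-rate and folded-MAF (`min(f̄, 1−f̄) > 0.05`) filters, mean
  imputation, and a grid search over depth × missing-rate thresholds that
  picks the most discriminating configuration.
- **Morphophysiological criterion** — per-trait RCBD ANOVA with Fisher's
  LSD at *p* < 0.01 (`LSD = t(1−α/2, df_e)·√(2·MSE/B)`), the angular
  transform `asin(√y)` for plot proportions, the 1.5-unit rule for 1–9
  ratings, and union combination across traits.
- **PCA + sequential ANOVA criterion** — centered PCA of the bulk × marker
  frequency matrix, then a one-way ANOVA with LSD on the cultivar scores of
  each PC axis in turn (bulks as replicates, `df_e = S − C`), stopping after
  three consecutive axes that add no newly distinct pair.
- **Discriminant criterion** — per pair, PCA of its six bulks, then a
  pseudo-inverse linear discriminant trained on two bulks per cultivar and
  validated on the third (each bulk predicted exactly once), over k = 1..5
  axes; distinct only on 6/6 correct classification.
- **AMOVA criterion** — Nei's (1972) distance
  `D = −ln(J_XY/√(J_X·J_Y))` between bulks, two-group AMOVA on squared
  distances with permutation or exhaustive Φ_ST p-values. With 3 bulks per
  cultivar the exhaustive minimum p is 2/20 = 0.1, so this criterion can
  never reach *p* < 0.05 — an analytic property the package reproduces.
- **Cluster criterion** — UPGMA on the correlation distance `1 − r`, with
  multiscale-bootstrap approximately unbiased (AU) support
  (`AU = 1 − Φ(v − c)` from the fit `Φ⁻¹(1−BP_r) ≈ v√r + c/√r`); a cultivar
  is completely distinct when its bulks form an exclusive clade with
  AU ≥ 0.95.
- **Consistency layer** — Mantel tests and classical MDS (with Kruskal
  stress-1) across trait and marker distance matrices, and Table-style
  summaries over criteria and their union combinations.

## Worked example

Simulate a DArTag-like panel for 8 moderately differentiated cultivars
(F = 0.02, three 200-plant tetraploid bulks each), filter, and run the
criteria:

```r
library(dustinct)
cfg <- marker_sim_config(n_cultivars = 8, panel = "dartag",
                         n_markers = 800, fst = 0.02, seed = 11)
sim <- simulate_marker_dataset(cfg)
ff  <- apply_filter_config(sim$counts, filter_config(min_reads = 20, max_missing = 0.30))
ff
#> filtered_freqs [reads>=20_miss<=0.3_maf>0.05]: 646 markers retained (of 800), mean depth 580.5

res <- pca_anova_distinctness(ff$freq, sim$meta)
res
#> Distinctness result [pca_anova]
#>   8 cultivars, 28/28 distinct pairs (100.0%)
#>   8 completely distinct cultivar(s): A, B, C, D, E, F, G, H

amova_all_pairs(ff$freq, sim$meta)
#> Distinctness result [amova]
#>   8 cultivars, 0/28 distinct pairs (0.0%)
#>   0 completely distinct cultivar(s)
```

The PCA-ANOVA criterion separates every pair (26 pairs on PC 1, the last
two on PC 2), while the AMOVA criterion separates none — not for lack of
signal, but because its exhaustive permutation floor at three bulks is
p = 0.1. Combining with a simulated trait trial:

```r
tt <- simulate_trait_table(trait_sim_config(n_cultivars = 8, seed = 12))
mo <- morpho_distinctness(tt)
summarize_distinctness(list(morpho = mo, dartag_pca = res))
#>          criterion n_distinct_pairs pct_distinct_pairs n_completely_distinct pct_completely_distinct
#>             morpho               27               96.4                     6                      75
#>         dartag_pca               28              100.0                     8                     100
#>  morpho+dartag_pca               28              100.0                     8                     100
```

Here the columns give, per criterion and for the union combination, the
number and percentage of distinct pairs among the 28 pairwise comparisons
and the number and percentage of cultivars distinct from all others.

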