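---
title: "Deciding variety distinctness from bulked-sample allele frequencies and spaced-plant trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding variety distinctness from bulked-sample allele frequencies and spaced-plant trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dustinct)
```

## The statistical problem

Outbred crops such as alfalfa are marketed as synthetic varieties: each
cultivar is a heterogeneous population characterized by allele frequencies,
not by a genotype. A candidate variety is registrable only if it is
*distinct* — statistically distinguishable from every registered variety.
`dustinct` implements two families of distinctness evidence over a common
verdict structure (a symmetric boolean pair matrix plus per-pair evidence):

1. **morphophysiological**: plot-level traits from a randomized complete
   block design (RCBD) of spaced plants;
2. **molecular**: SNP allele frequencies of independent bulks of pooled
   plants, where the bulks of a cultivar act as its replicates.

The central experimental design is 18 cultivars × 3 bulks of 200 plants,
genotyped at a GBS-like (many markers, shallow depth) or a DArTag-like (few
markers, deep) panel, plus an 8-trait RCBD trial in 4 blocks of 25-plant
plots. All defaults in the package reflect those conditions.

## Data model and filtering

Read counts live in a `read_count_matrix` (paired ref/alt integer matrices,
samples × markers); a cell with zero total depth is *missing* — never a
sentinel frequency. `apply_filter_config()` runs a fixed five-stage
pipeline:

1. cells with depth `< min_reads` become missing;
2. frequency `alt/(ref+alt)` for surviving cells;
3. markers with missing fraction `> max_missing` are dropped;
4. markers whose folded mean frequency `min(f̄, 1−f̄)` is `≤ maf_min`
   (mean over non-missing samples, default 0.05, strict comparison) are
   dropped;
5. residual missing cells are imputed with the marker mean.

Two interpretations of "minimum reads per locus" were possible: a per-cell
mask or a per-marker average. The per-cell reading is used because it makes
the depth and missing-rate filters interact the way a depth × missing-rate
grid presupposes (stricter depth ⇒ more missing cells ⇒ fewer markers
survive stage 3); the alternative would make the two axes of the grid
nearly independent. Mean imputation is chosen for stage 5 because PCA and
the distance measures need complete data and mean imputation is
deterministic and conserves each marker's mean frequency exactly (a tested
invariant). MAF is computed *after* depth masking, so the "average
frequency over all samples" refers to the data actually analyzed.

`grid_search()` evaluates a distinctness criterion under every
configuration (default 4 depth × 5 missing-rate thresholds = 20) and picks
the configuration with the most distinct pairs; ties break toward more
completely distinct cultivars, then fewer retained markers (parsimony),
then enumeration order. On strongly differentiated data many configurations
saturate and the parsimony tie-break governs.

## Morphophysiological criterion

Each quantitative trait gets a two-way additive RCBD ANOVA (cultivar +
block; error df `(C−1)(B−1)`), fit via `stats::aov`. Plot *proportions*
(e.g., fraction of plants with variegated flowers) are angular-transformed,
`y' = asin(√y)`, before fitting; reported means stay on the analysis scale
(the transform is monotone, so back-transforming means with `sin²` cannot
change a distinctness call). A pair differs for a trait when its mean
difference *strictly* exceeds Fisher's LSD at the two-sided working level
`α = 0.01`:

$$\mathrm{LSD} = t_{1-\alpha/2,\,df_e}\sqrt{2\,\mathrm{MSE}/B}.$$

Traits scored on a discrete 1–9 scale (growth habit) instead use the
rating rule: cultivar means differing by more than 1.5 units. The per-trait
matrices combine by union; a cultivar distinct from all others is
*completely distinct*. Two open choices were resolved as follows: the LSD
is *unprotected* (no global F gate), since the pairwise rule is applied
directly in DUS practice; and the rating rule operates on plot means, the
same summary used by the ANOVAs.

## PCA + sequential per-axis ANOVA

The most sensitive molecular criterion. The bulk × marker frequency matrix
is column-centered (no variance scaling — frequencies share a common
scale, and scaling would up-weight markers hovering near the MAF
threshold) and decomposed by SVD; each axis is oriented so its
largest-magnitude loading is positive, which makes score signs invariant
to marker permutation. For each axis in order, a one-way ANOVA on the
cultivar scores uses the between-bulk variation as error (`df_e = S − C`,
e.g. 54 − 18 = 36) and calls pairs by the same strict LSD rule with `b`
bulks as the replicate count. Unbalanced bulk counts fall back to per-pair
LSDs with harmonic-mean replicate numbers (flagged).

"Failing to observe cultivar differences for three subsequent axes" is the
stopping rule; an axis *observes differences* when it adds at least one
previously non-distinct pair. An alternative reading — any significant
cultivar F — is implemented behind `stop_rule = "significant_F"`; the
new-pairs reading is the default because the scan explicitly tracks which
pairs remain open at each axis. Axes with eigenvalue below 1e-12 are never
scanned. A Shapiro–Wilk check per axis is provided as a report-only
diagnostic; it never alters calls.

## Discriminant criterion

Per pair, a fresh PCA is computed on the pair's six bulks only (not
subsetted from the global PCA — the dimensionality reduction is part of the
per-comparison procedure), keeping at most 5 axes. Three validation rounds
hold out the bulk with matching index from each cultivar, train a
two-class linear discriminant on the remaining four, and predict the two
held-out bulks — so each bulk is predicted exactly once. With two training
samples per class the pooled within-class covariance is singular for
k > 2; the Moore–Penrose pseudo-inverse is used, which reduces to
nearest-centroid in the null directions, and exact ties go to the
alphabetically first cultivar. The pair is distinct when all six
predictions are correct for at least one k ∈ 1..5 (whether a specific k or
any k was intended is ambiguous; "any k" is adopted, which is the more
liberal and the more natural reading of scanning k upward).

## AMOVA criterion and its analytic failure at three bulks

Nei's (1972) standard distance is computed directly from bulk frequencies
(the bulks are frequency estimates, not genotype samples, so the 1978
small-sample correction does not apply). The two-group AMOVA partitions
squared distances; Φ_ST is tested by permuting the bulk-to-cultivar
assignment. When `choose(N, n) ≤ 10000` the permutation distribution is
enumerated exhaustively, which makes the p-value deterministic; otherwise
`nperm` random assignments are drawn and the add-one estimator
`(b + 1)/(nperm + 1)` is used.

With three bulks per cultivar there are only `choose(6, 3) = 20`
assignments, and the observed split and its mirror always attain the
maximal Φ_ST, so the minimum attainable p-value is 2/20 = 0.1 — above any
conventional α = 0.05. The criterion therefore declares **zero** distinct
pairs on *any* 3-bulk dataset, however separated; with four bulks the floor
drops to 2/70 ≈ 0.029 and the criterion becomes usable. The package
reproduces this as an analytic property (exhaustive enumeration in the test
suite), which is the clean explanation of the criterion's empirical failure
at three replicates.

## Cluster criterion with multiscale-bootstrap AU support

Bulks are clustered by UPGMA (`stats::hclust`, average linkage) on the
correlation distance `d = 1 − r` (the plain form, not `√(2(1−r))`,
matching common practice for frequency profiles). Cluster support uses the
multiscale bootstrap: at each relative size `r ∈ {0.5, …, 1.4}` (step 0.1),
`B = 1000` marker resamples of size `round(r·M)` are drawn with
replacement, the tree is rebuilt, and each observed node's bootstrap
probability `BP_r` (exact leaf-set recovery) is recorded. The
approximately unbiased value comes from the weighted least-squares fit

$$\Phi^{-1}(1 - BP_r) \approx v\sqrt{r} + c/\sqrt{r}, \qquad
\mathrm{AU} = 1 - \Phi(v - c),$$

with binomial-variance weights and BP clamped to `[0.5/B, 1 − 0.5/B]`.
Nodes recovered in every resample get AU = 1; a degenerate fit falls back
to BP at r = 1 (flagged). "1000 replications" is read as per scale (10,000
resamples total), matching the defaults of the standard multiscale
implementation. A cultivar is completely distinct when a node's leaf set
equals *exactly* its bulk set with AU ≥ 0.95 — exclusivity is strict, so a
clade containing one foreign bulk does not count. This criterion makes no
pairwise calls; its output is the completely-distinct list, and AU values
can be exported as newick node labels (`write_newick_au()`, AU × 100).

## Consistency layer

Cultivar profiles are mean bulk frequencies (marker layers; no
standardization, common scale) or z-standardized cultivar trait means
(trait layer; traits mix days, cm and fractions, so unstandardized
Euclidean distances would be dominated by whichever trait has the largest
units). Mantel tests (delegated to `vegan::mantel`; one-sided upper
p-value, consistency being the alternative) compare layer distance
matrices; classical MDS (`stats::cmdscale`) embeds them, with Kruskal
stress-1 quantifying fit per dimension — stress-1 is adopted as "the"
stress statistic since several variants exist and none is canonical for
principal coordinates.

## The synthetic-data generator

The generator defines the study conditions the tests run under:

- **Cultivar frequencies**: Balding–Nichols — ancestral `p ~ Beta(0.7, 0.7)`
  (a mildly U-shaped SNP spectrum), cultivar frequency
  `~ Beta(p(1−F)/F, (1−p)(1−F)/F)`. The single parameter `F` maps onto
  F_ST; the default 0.05 is a typical among-variety differentiation for
  alfalfa. `F = 0` yields identical cultivars (the null).
- **Bulks**: a bulk of `n` plants with ploidy 4 carries `4n` allele copies;
  the bulk frequency is `Binomial(4n, p)/4n`. This finite-sampling noise is
  the only within-cultivar variance source — the model deliberately has no
  separate between-plant variance term, since none is identifiable from
  bulk data.
- **Read counts**: depth `~ NegBin(mean, size = 5)` (overdispersed, as GBS
  depth distributions are), `alt ~ Binomial(depth, bulk freq)`, cells
  zeroed with the panel's missing rate. Panel presets: `"gbs"` (17,937
  markers, depth 56, 10% missing) and `"dartag"` (1,770 markers, depth 579,
  1% missing).
- **Traits**: cultivar means are multivariate normal with the built-in
  8-trait correlation matrix (dominated by the winter-activity syndrome:
  height and stem-length traits mutually correlated at 0.82–0.98 and
  anti-correlated with onset of flowering; verified positive definite) and
  per-trait means/SDs sized so cultivar ranges look like a real DUS trial.
  Plot values add one block effect per block per trait (SD = 0.2 × the
  between-cultivar SD) and a plot error (SD = 0.4 ×); ratings are rounded
  and clipped to [1, 9], proportions realized as
  `Binomial(25, p)/25`. The within-trial SDs are package choices — no
  within-trial variances are published for the reference design.

Determinism is contractual: the same seed gives bit-identical output, and
derived seeds isolate the stages so changing, say, the depth model does not
perturb the cultivar frequencies.

**What passing tests do and do not show.** The generator emulates the
sampling *structure* (finite bulks, overdispersed depth, RCBD blocks,
correlated traits) but not linkage disequilibrium, ascertainment bias,
selection, pedigree relatedness, or any genetic link between the marker and
trait layers — the two layers are simulated independently, so cross-layer
Mantel correlations are near zero by construction, unlike in real data
where they are modest but positive. Calibration results (null rejection
rates, power curves) therefore validate the statistical machinery, not
field performance.

## Numerical choices and degenerate inputs

- Strict inequalities throughout (`> LSD`, `> 1.5 units`, MAF `> 0.05`):
  boundary equality is never distinct/retained.
- Zero error mean squares (perfect fits) are flagged; every unequal pair of
  means is then called distinct rather than dividing by zero.
- Nei distances between oppositely fixed profiles are infinite; they are
  capped above the largest finite distance and flagged.
- Exhaustive AMOVA enumeration auto-engages when `choose(N, n) ≤ 10000`.
- PCA axes with eigenvalue `< 1e-12` are never scanned; UPGMA ties follow
  `stats::hclust`'s deterministic ordering.
- Permutation p-values use add-one estimators and never return 0.

## Problem sizes used by the test suite

The suite exercises study-scale structure at reduced marker counts chosen
as adequate for the properties under test: null calibration uses 200
replicates of 18 cultivars × 2,000 markers at depth 60 (the per-axis LSD
null rate sits at ~1% and the full sequential scan below 15%); power curves
use the full DArTag-like panel over `F ∈ {0, 0.002, 0.01, 0.05}`; oracle
checks (Nei, UPGMA, AMOVA, LSD, MDS) run on ≤ 8-entity toys against
brute-force reimplementations at 1e-8. The acceptance script runs the
full-size panels end to end.

## Known limitations

- Single-cycle trials only: no cultivar × year interaction term (COYD-style
  multi-year analysis is out of scope).
- The AMOVA and discriminant criteria assume equal bulk counts per
  cultivar; the PCA-ANOVA criterion tolerates imbalance via harmonic-mean
  LSDs.
- AU support is computed for the observed tree's nodes only; no consensus
  tree is built.
- VCF ingestion takes biallelic records only (first ALT's allele depth);
  multiallelic sites are skipped with a warning.
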