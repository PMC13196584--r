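---
title: "Methods: genome-resolved CSR life-history classification"
author: "csrtraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-resolved CSR life-history classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrtraits)
suppressPackageStartupMessages(library(SummarizedExperiment))
```

## Scope and model

`csrtraits` analyses replicated disturbance-frequency experiments in which
communities of genomes (MAGs) are observed as coverage-derived abundance
tables together with per-genome COG functional-category gene counts. Three
regime classes structure all inference: **undisturbed** (frequency 0),
**intermediate** (pulse disturbances) and **press** (disturbance every
cycle). The working hypothesis encoded in the strategy map is that
competitors (C) are favoured in the undisturbed regime, ruderals (R) at
intermediate frequencies and stress-tolerants (S) under press disturbance.

The package treats the *assignment machinery* — not any particular
biological conclusion — as its product: everything downstream of the count
tables is computed by the package itself and is validated against planted
ground truth from the built-in generator.

## The synthetic community generator

`simulateCsrExperiment()` emulates the standard study design: 6 disturbance
levels at frequencies 0, 1/8, 1/6, 1/4, 1/2 and 1 events/day, 5 replicate
reactors per level, sampled at day 42 (all configurable through
`disturbanceDesign()`). Levels map to regimes as L0 → undisturbed,
L1–L4 → intermediate, L5 → press; the intermediate fitness bonus is applied
uniformly to L1–L4 because contrasts are made at the regime, not level,
scale.

**Trait profiles.** Each genome draws a total COG-annotated gene count
uniformly in 1500–4000 and allocates it multinomially over 19 categories
from a baseline composition chosen to resemble a typical bacterial genome.
For a strategy genome, every category linked to its strategy (default map:
Q, I → C; K, P → R; F, D, L, T, J → S; E, M → CR; V → CS) has its baseline
probability multiplied by `1 + traitEffect` before renormalisation. The
default 19-letter alphabet (C D E F G H I J K L M N O P Q S T U V) covers
all categories in the default map and omits the rare or poorly-populated
COG classes (A B R W X Y Z); both alphabet and map are arguments, because
annotation pipelines differ in which classes they report.

**Abundances.** The expected relative abundance of genome *g* at level *l*
is proportional to `base_g · exp(fitnessEffect · 1[strategy(g) matches
regime(l)])`, with log-normal baselines `base_g` (sdlog 0.6). Each sample's
composition is drawn Dirichlet with total concentration 200 around that
expectation, and counts are multinomial at a log-normal depth (mean
2 × 10⁴, CV 0.3). The concentration and depth defaults are package
choices — the variance structure of real MAG abundance tables is not
something the analysis itself pins down — selected to give replicate-level
compositional noise comparable to what replicated bioreactor MAG tables
show (between-replicate Bray-Curtis ≈ 0.1–0.3 within a level at the
default effect).

**Genome sizes** are log-normal with strategy-specific parameters:
competitors largest location and smallest scale (meanlog log 4.1 Mbp, sdlog
0.15), ruderals smallest location (log 3.7 Mbp, 0.18), stress-tolerants the
widest scale (log 3.9 Mbp, 0.35). The differences are deliberately subtle:
at default class sizes a Welch ANOVA on the sizes is typically
non-significant, mirroring the qualitative (not statistical) nature of the
expected pattern; inflate the gaps explicitly if a significant contrast is
wanted.

**Function metrics** (TKN and COD removal %, −SVI, effluent nitrate) are
Gaussian with regime-dependent means: best nitrogen removal and settling at
intermediate levels, highest nitrate but poorest settling when undisturbed,
poorest nitrogen removal under press. They exist to make overlay vectors
recoverable in constrained ordinations.

**Determinism.** One master seed fans out to per-stage child seeds via
`child_k = (7·seed + 10007·k) mod (2³¹ − 1)`, so traits, abundances,
function metrics and quality metadata are independently reproducible. All
seeded functions snapshot and restore the caller's RNG state.

What the generator does *not* emulate: read-level sequencing error,
assembly/binning artefacts, taxon-specific covariance beyond the planted
strategy structure, temporal succession, or genuinely compositional
interactions (cross-feeding, inhibition). Passing tests therefore certify
the statistical machinery under a known truth — they do not certify that
any real community follows the CSR map.

## CSR assignment

The enrichment statistic for feature *x* and regime *r* is
`T_r = mean(x | r) − mean(x | not r)`. The null re-draws `T_r` under
unrestricted permutations of the sample-to-regime labels (all regimes share
each permutation), with one-sided p-values `(b + 1)/(m + 1)` where ties
count as exceedances — the estimate is never 0 and is valid for any number
of permutations. The reference tool this emulates describes itself only as
"simulation-based"; the label-permutation null is this package's explicit
definition, and a parametric multinomial bootstrap (`null = "multinomial"`)
is provided as an alternative backend for count-derived features.

Benjamini-Hochberg adjustment is applied across the *full feature × regime
family* (the scope is a documented choice; adjust per-regime by splitting
the result table if preferred). A feature's strategy set collects the
regimes with `q ≤ α` (default α = 0.05), written in fixed order C < R < S;
an empty set is `"unassigned"`. Only enrichment (not depletion) drives
labels, since the strategy map keys on where a trait *peaks*; depletion
shows up as effects near −1·enrichment elsewhere and is visible in the
result table. Testing is at the regime scale (3 classes, matching how
results are grouped); per-level testing amounts to passing level labels as
the `regimes` argument.

With the default synthetic conditions (60 genomes, fitness effect 2) all
45 planted strategy genomes recover exactly their true single letter and
the neutral false-assignment rate stays near the BH-implied level (the
binomial spread at 15 neutral genomes is wide — roughly 0–2 labelled per
run across seeds).

## Distance-based multivariate machinery

All of this is implemented from first principles in the package, with
`vegan` used only as an independent cross-check in the test suite.

- **Distances.** Samples are closed, square-root transformed, and compared
  with Bray-Curtis. PCoA eigen-decomposes `G = −½·C·D²·C`; negative
  eigenvalues are retained and flagged.
- **PERMANOVA** (one-way, fixed factor): `SS_total = Σ_{i<j} d²_ij / N`,
  within-group sums analogous, pseudo-F with `(g − 1, N − g)` degrees of
  freedom, unrestricted label permutation. On ≤ 8 samples the permutation
  p agrees with exhaustive enumeration (tested each build).
- **PERMDISP**: distances to group centroids in the PCoA embedding with
  the negative-eigenvalue correction (imaginary axes subtract; squared
  distances floored at 0), one-way F, permutation of the residual
  distances. Its rejection rate under equal dispersion is checked at the
  nominal 5% level over 500 simulated datasets.
- **CAP**: discriminant analysis of groups on the first *m* PCoA axes;
  when *m* is unspecified it maximises leave-one-out allocation success
  with the smallest *m* on ties (the reference analyses do not report how
  *m* was set, so the criterion is pinned here and reported alongside the
  result).
- **DistLM**: McArdle–Anderson partitioning `SS_explained = tr(HGH)` with
  a pseudoinverse-based hat matrix (rank-deficient predictor sets are
  tolerated, not errors). Selection is bidirectional stepwise —
  alternating best addition and best removal, accepting only strict
  decreases of `AICc = N·ln(SS_res/N) + 2vN/(N − v − 1)` with `v` =
  predictors + intercept. The AICc form and the bidirectional search are
  pinned, documented choices (the criterion's name alone does not fix
  either), and the per-step trace is returned for audit. A non-positive
  residual trace (possible under semi-metric distances or saturation)
  makes a candidate ineligible rather than producing an undefined
  criterion.
- **dbRDA** eigen-analyses the fitted component `HGH`; constrained-axis
  variation sums exactly to the model's explained variation (tested to
  1e−8). Overlay vectors keep variables whose two-axis Pearson correlation
  vector has length `> rMin` (default 0.20); the threshold applies to the
  vector norm, since per-axis conventions are ambiguous in common usage.
- **Similarity groupings** come from UPGMA on the dissimilarities cut at
  `1 − threshold/100` (default 85% similarity).

## SparCC networks and modules

Basis correlations are estimated from log-ratio variances
`t_ij = var(log x_i / x_j)` under the sparsity assumption, solving the
linear system for basis variances, then iteratively excluding the most
strongly correlated pair (`|ρ|` above 0.1, up to 10 exclusions, each
component kept in ≥ 3 pair equations). Per resample, fractions are drawn
from a Dirichlet with the observed counts plus a 0.5 pseudocount per cell —
zero replacement and closure in one step — and the final estimate is the
element-wise median over 20 resamples with an exact unit diagonal.
Estimation is joint across all samples (not within regimes); that scope is
a flagged default.

Networks keep positive associations at `ρ ≥ 0.20` (inclusive; an
absolute-value mode exists). Louvain modules are found with igraph's
multi-level optimiser (seeded, with a resolution parameter); the reported
Q is recomputed by the package's own independent modularity evaluator, so
optimiser and evaluator can never silently disagree. Modules map to the
regime where their members' summed relative abundance has the largest
mean; exact ties break to undisturbed < intermediate < press and are
flagged.

## Pipeline, I/O and problem sizes

`runPipeline()` chains: load or simulate → (amplicon mode) rarefaction to
5089 reads → √-transformed Bray-Curtis → PERMANOVA/PERMDISP/CAP → CATs and
level Z-scores → CSR assignment of genomes and traits with Venn accounting
→ Welch ANOVA of genome sizes across assigned strategies → DistLM + dbRDA
on CAT predictors with overlays → SparCC network, Louvain modules, regime
mapping → tab-separated report plus a run log recording every seed,
permutation count and threshold. Two entry modes mirror the two data
streams such experiments produce: `"mag"` (coverage-derived tables used as
given) and `"amplicon"` (integer counts rarefied first). Z-scores are
computed over level means rather than individual samples (matching
level-resolved heatmaps); per-sample scoring is a config switch.

Rarefaction subsamples reads without replacement to exactly the target
depth and *drops* samples below it (listing them), rather than silently
passing them through. Genes annotated with several COG letters contribute
one count to each letter by default (`"fractional"` splits 1/n); the
category alphabet is configurable.

Default problem sizes in the tests and the acceptance script — 60 genomes
× 30 samples for the study-scale bundle, 500 features for null
calibration, 30 genomes × 200 samples for SparCC recovery, 500 datasets
for PERMDISP calibration, 999–9999 permutations — are the package's chosen
verification scale: large enough for the calibration and recovery bands
being asserted, small enough to run on a laptop in minutes.

## Known limitations

- The enrichment null assumes exchangeable samples across regimes; strong
  depth confounding with regime would require a stratified null.
- CAP's LOO criterion can overfit m when groups are tiny; the trace is
  returned so users can inspect the success curve.
- SparCC assumes most pairs are uncorrelated; dense planted correlation
  structure biases basis variances (the exclusion heuristic mitigates but
  does not remove this).
- The CSR map is a hypothesis about regimes, not a property of the
  statistics; in systems where the regime → strategy correspondence
  differs, relabel via a custom trait/strategy map.

## Session

```{r}
sessionInfo()
```
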