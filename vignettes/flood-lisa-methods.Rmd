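---
title: "Methods: spatial clustering of flood risk, inequality, and chronic disease"
author: "floodlisa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial clustering of flood risk, inequality, and chronic disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodlisa)
```

## The problem

Flood damage is not distributed evenly: neighborhoods shaped by racial
residential segregation and economic inequality are more likely to sit in
flood-prone areas and less able to absorb the health and financial shocks
of a flood. `floodlisa` implements the tract-level spatial workflow used
to locate such compound-burden areas: per-property ordinal flood-risk
scores are summarized into tract proportions, inequality is measured with
the Index of Concentration at the Extremes (ICE), and bivariate local
indicators of spatial association (LISA) identify tracts where high flood
risk is surrounded by high inequality or high chronic-disease prevalence.
The package ships a fully seeded synthetic census-tract generator so the
whole pipeline is testable end to end without any proprietary data.

## Tract-level variables

**Flood risk.** Each property carries an ordinal FloodFactor score 1–10.
A tract's exposure is summarized as the proportion of low (FF ≤ 2),
moderate (3 ≤ FF ≤ 6), and high (FF ≥ 7) risk properties; sensitivity
variants use the share at exactly one level (FF7–FF10). Tracts with zero
properties are flagged missing and excluded from spatial fits with a
logged count — never imputed as zero.

**ICE.** For privileged count $A$, deprived count $P$, and total $T$,

$$\mathrm{ICE} = \frac{A - P}{T} \in [-1, 1],$$

where $-1$ means the entire population sits in the deprived extreme. The
three variants follow the standard definitions: income (households
≤ \$25,000 vs ≥ \$125,000), race (Black or non-white Hispanic vs white
residents), and the race–income cross. Note that some applied write-ups
swap the letter names of the two groups while keeping this range
interpretation; `ice()` therefore uses explicit `privileged`/`deprived`
argument names rather than $A$/$P$. All ICE vectors are **inverted**
(multiplied by $-1$) by `compute_indices()` so that *higher values mean
greater inequality*: an HH cluster then always reads "high flood risk
surrounded by high inequality".

**Sensitivity measures.** The Gini coefficient is estimated from grouped
bracket counts with the midpoint convention (open-top bracket valued at
1.5× its lower bound); this is a stated estimator choice, since the
metric is conventionally named without one. The Index of Dissimilarity
requires subunits, which a single tract does not have; the package's
convention computes $D$ within each enclosing region (the generator emits
lattice quadrants as synthetic "counties") over its tracts and assigns
every tract its region's $D$. Both choices are deliberate, documented
conventions, not field standards.

## Spatial weights

Queen contiguity: two tracts are neighbors iff their boundaries share at
least one point, including a single corner; the diagonal is always zero,
and tracts with no neighbors are recorded as islands. Detection uses
exact segment predicates (orientation tests plus collinear-overlap
checks), with an optional `tolerance` for imperfectly snapped real-world
geometry; the default of 0 is exact for lattice and grid-snapped
polygons.

Row standardization is applied by default. The underlying study software
tradition defaults to it, and it yields the clean identity
$\operatorname{mean}_i(I_i) = I$ used throughout the test suite; binary
weights remain available (`style = "B"`). Islands are excluded from
standardization, statistics, and inference, and surface as an `ISLAND`
label — they never silently receive p-values.

## Moran statistics and inference

With population-standardized variables ($\sum_i z_i^2 = n$),

$$I = \frac{n}{S_0}\,\frac{\sum_{ij} w_{ij} z_{x,i} z_{y,j}}{\sum_i z_{x,i}^2},
\qquad I_i = z_{x,i} \sum_j w_{ij} z_{y,j},$$

univariate when $z_y = z_x$, bivariate otherwise. The bivariate form is
directional by construction: the left-hand (focal) variable is flood
risk; the right-hand variable supplies the spatial lag. Inference is by
conditional permutation: each tract's focal value is held fixed while the
*other* tracts' $z_y$ values are randomly reassigned to its neighbor
positions; only the lagged variable is permuted (the alternative of
permuting the pair jointly is a different null and is not the default).
The pseudo p-value is $(R+1)/(M+1)$ with $R$ the number of permuted
statistics at least as extreme as the observed one.

Three numerical details matter:

* **Tie counting.** Permuted sums of the same values in a different order
  can differ from the observed statistic by one ulp; "at least as
  extreme" counts such ties within a $10^{-10}$ relative tolerance.
  Without this, discrete permutation distributions (small $n$, equal
  weights) lose tied mass and the p-values are biased low against exact
  enumeration.
* **Seeding.** Each tract draws from an RNG substream derived from
  `(seed, tract index)`, so p-values are independent of evaluation order
  and identical across repeated runs.
* **Tie rule for quadrants.** The sign reference is the standardized mean
  ($z = 0$); an exact zero in the focal value or the lag is classified
  `NS` regardless of significance. This is deterministic and matches the
  mean-centered Moran scatterplot convention.

**The directed one-sided convention and its calibration.** The default
`alternative = "directed"` counts extremeness in the direction of the
observed statistic — the convention of the dominant desktop tooling for
LISA maps. Users should understand its null behavior: because the
direction is chosen *after* seeing the statistic, it behaves like a
two-tailed test at twice the nominal level. On spatially random data
about 10% of tracts reach $p < 0.05$ (the package's own calibration run:
0.0998 over 50 seeds on a 15×15 lattice at $M = 999$), while the
`"two.sided"` option is calibrated at its nominal level (measured 0.0500
under the same conditions). The directed default is retained for
comparability with published LISA maps; analyses that need nominal
type-I control should pass `alternative = "two.sided"` or read the maps
at stricter thresholds ($p < 0.01$, $p < 0.001$), which is also why
results are reported at three levels. No multiple-testing correction is
applied by default, matching the reporting convention of cluster-map
studies; `stats::p.adjust` can be applied to `fit$p` by users who want
FDR control.

Significance levels are supplied as a vector (default trio 0.05, 0.01,
0.001); the first is primary and the others produce extra label columns,
so the stability of cluster locations across thresholds is directly
inspectable.

## The synthetic generator

`synthesize_tracts()` emulates the *structure* of the real inputs — a
polygon tessellation, spatially autocorrelated demographic composition,
bracketed household incomes, ordinal per-property flood scores, chronic
condition prevalences, rural–urban codes — with every draw flowing from
one seed. Latent fields are simultaneous-autoregressive (SAR) draws,
$u = (I - \rho W)^{-1}\varepsilon$, standardized to unit variance: SAR
was chosen over CAR or Gaussian-process fields because it is closed-form,
cheap, and parameterized by the same $W$ the analysis uses, so simulated
autocorrelation is directly interpretable. Planted rectangular blocks
shift the flood and deprivation propensities by a stated number of
standard deviations, planting a joint cluster the bivariate LISA should
recover.

Counts are deterministic rounded logistic transforms of the latent
fields (binomial draws behind `stochastic_counts = TRUE`): the
deterministic default keeps parameter-recovery tests low-variance.
FloodFactor scores bin per-property latent values at the fixed decile
edges of the standard normal, so all ten levels occur at background
settings. RUCA codes grow 1–10 along concentric rings from the lattice
center, and the base population tapers from the urban center (about 3×
the rural edge), giving the profiling tables a realistic density
gradient. Prevalences are logistic transforms of a health propensity
that loads 0.6 on the deprivation field — chronic-disease burden tracks
deprivation in the emulated inputs.

**Reference conditions** (the package defaults, fixed before any test
was run and not revisited): a 20×20 lattice of one-square-mile tracts,
$\rho = 0.6$, one 6×6 planted block with flood and inequality effects of
2 SD, 40 properties per tract, base population 4,000. Under these
conditions the bivariate LISA recovers on average 84% of planted-block
tracts as HH at $\alpha = 0.05$ (20 seeds, $M = 999$); the tracts it
misses sit mostly on the block perimeter, where part of the neighborhood
is background — a real property of boundary tracts, not an artifact.

**What passing tests do not show.** The generator's fields are smooth
logistic transforms with a single autocorrelation scale; real tract data
have survey noise, heavy-tailed income distributions, irregular polygon
shapes with varying neighbor counts, and genuinely multivariate
dependence among race, income, and health. Recovery and calibration
results under the generator therefore validate the *machinery*, not any
claim about the sensitivity of the method on real data.

## Sizes and budgets used in validation

Simulation-based checks use deliberately modest problem sizes chosen as
the package's own validation design: exact permutation enumeration at
$n = 6$ (720 global and 120 conditional arrangements), oracle
equivalence on 25 random 10×10 lattices, null calibration with 50 seeds
on a 15×15 lattice at $M = 999$, and planted-cluster recovery with 20
seeds at the reference conditions. The conventional reporting choice for
real analyses is $M = 9999$ permutations; the identical machinery is
exercised at smaller $M$ in the test suite, and $M$ only changes the
granularity floor $1/(M+1)$ of the pseudo p-values, not the algorithm.

## Known limitations

* Polygons are single rings: no holes, no multipolygons. Real tract
  shapefiles occasionally need both; pre-dissolving such tracts is the
  workaround.
* The Gini and IOD conventions above are choices among several defensible
  estimators; comparisons across software should expect small systematic
  differences.
* The profiling t-tests are Welch two-sample comparisons of member vs
  non-member tracts (unweighted tract-level means). Published tables in
  this literature are often ambiguous about pooling and weighting; the
  one-sample-vs-fixed-mean mode and population weighting are provided as
  flags.
* `run_all()` writes plain CSV/GeoJSON/GAL only; there is no shapefile
  writer and no cartographic output beyond `plot(fit, type = "map")`.
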