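# floodlisa

Tract-level spatial analysis of flood risk, neighborhood inequality, and
chronic-disease prevalence.

Communities shaped by racial residential segregation and economic
inequality are disproportionately exposed to flooding and less able to
recover from it. `floodlisa` is for epidemiologists and spatial analysts
who want to locate such compound-burden areas: it builds
queen-contiguity spatial weights from tract polygons, computes the
standard inequality and flood-exposure indices, and fits univariate and
bivariate **local Moran's I (LISA)** with conditional-permutation
inference, classifying each tract into the familiar
high-high / low-low / high-low / low-high cluster typology.

## The statistics at its core

For population-standardized variables (so that `Σ zᵢ² = n`) and spatial
weights `w_ij` (queen contiguity, zero diagonal, row-standardized by
default):

- global (bivariate) Moran's I: `I = (n/S₀) Σ_ij w_ij z_x,i z_y,j / Σ_i z_x,i²`
- local Moran's I: `I_i = z_x,i · Σ_j w_ij z_y,j`

with `z_y = z_x` giving the univariate statistics. In the bivariate
form the focal variable `x` is the proportion of high flood-risk
(FloodFactor ≥ 7) properties and `y` supplies the spatial lag — an
inverted Index of Concentration at the Extremes
(`ICE = (privileged − deprived)/total`, inverted so higher = more
unequal), a chronic-condition prevalence, a grouped-data Gini, or a
regional Index of Dissimilarity. Significance comes from conditional
permutation: tract i's focal value is held fixed while the other
tracts' `y` values are reassigned to its neighbor positions; the pseudo
p-value is `(R+1)/(M+1)`. Significant tracts with positive focal z and
positive lag are `HH` ("high flood risk surrounded by high
inequality"), and so on.

A fully seeded synthetic census-tract generator (SAR latent fields on a
polygon lattice, plantable joint flood/inequality clusters, ordinal
per-property flood scores, income brackets, prevalences, rural-urban
codes) makes the entire pipeline testable without proprietary data.

## Worked example

```r
library(floodlisa)

td  <- synthesize_tracts(sim_config(seed = 42))   # 20x20 lattice, one planted block
tab <- compute_indices(td)                        # ICE, flood shares, Gini, IOD
fit <- lisa(p_flood_high ~ ice_income, data = tab, weights = td$weights,
            permutations = 999, seed = 42, alpha = c(0.05, 0.01, 0.001))
fit
#> Local Moran's I (bivariate LISA)
#>   variables: p_flood_high ~ ice_income   tracts: 400 (0 islands)
#>   global Moran's I: 0.2228   permutations: 999   seed: 42
#>   clusters at alpha = 0.05: HH=50  LL=39  LH=16  HL=22  NS=273  ISLAND=0
```

The positive global I (0.22) says high flood risk and high economic
inequality cluster together spatially; 50 of 400 tracts are significant
HH tracts — high flood risk surrounded by high inequality — and 34 of
the 36 planted-block tracts (94%) are among them. Profiling compares HH
tracts with the rest of the study area:

```r
prof <- cluster_profile(fit, tab,
                        indicators = c("prev_asthma", "prev_diabetes",
                                       "hh_low_income"))
prof$membership
#>   cluster_type tracts population  density
#> 1           HH     50     182937 3658.740
#> 2           LL     39     128520 3295.385
#> 3           LH     16      50103 3131.438
#> 4           HL     22      68839 3129.045
#> 5           NS    273     849541 3111.872
#> 6       ISLAND      0          0       NA

prof$comparisons$HH[, c("indicator", "cluster_mean", "state_mean",
                        "delta", "stars")]
#>       indicator cluster_mean  state_mean        delta stars
#> 1   prev_asthma    0.1929096   0.1175800   0.07532953   ***
#> 2 prev_diabetes    0.2026622   0.1240975   0.07856472   ***
#> 3 hh_low_income  803.1800000 337.3500000 465.83000000   ***
```

HH tracts carry significantly higher asthma and diabetes prevalence
(about +7.5 and +7.9 percentage points over the study-area mean) and
more than twice the low-income household count — the compound-burden
pattern the method is designed to surface. `plot(fit)` draws the Moran
scatterplot; `plot(fit, type = "map", geometry = td$geometry)` maps the
clusters; `run_all(sim_config(seed = 42), out_dir = "out")` writes the
full result bundle (indices, every LISA fit, profiles, GAL weights, a
reproducibility manifest) as plain CSV/GeoJSON.

A thin command-line wrapper with `generate`, `indices`, `lisa`,
`profile`, and `run-all` subcommands lives at
`inst/cli/floodlisa.R` (requires `optparse`).

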