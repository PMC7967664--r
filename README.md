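# spatdrivers

Spatiotemporal driving-force analysis for areal pollutant panels in R.

Regional air-quality studies routinely ask two linked questions about a
pollutant field observed over administrative units (e.g. city-level PM2.5
concentrations in µg/m³): *where* does the pollutant cluster in space and
time, and *which* socio-economic and meteorological factors drive its
spatial heterogeneity? `spatdrivers` implements the full analysis chain
that this literature uses, as tested, composable R functions:

- **Spatial autocorrelation.** Global Moran's I with binary contiguity
  weights W,

  I = n Σᵢ Σⱼ Wᵢⱼ (xᵢ − x̄)(xⱼ − x̄) / (Σᵢ (xᵢ − x̄)² · S₀),

  with E[I] = −1/(n−1), randomization or normality variance,
  Z = (I − E[I])/√Var(I), and permutation inference; the local (LISA)
  decomposition Iᵢ with conditional-permutation significance and the
  hot-zone / cold-zone typology (H–H, L–L, H–L, L–H at |Z| ≥ 1.96 and
  ≥ 2.58).
- **Stratified-heterogeneity detection** (geodetector): the q-statistic
  q = 1 − Σₕ Nₕ σₕ² / (N σ²) over natural-breaks strata, with
  noncentral-F significance, plus the ecological (F-comparison) and
  interaction (overlay) submodels, and 10 km grid sampling of unit
  polygons.
- **Covariate screening**: Pearson correlation with single-linkage
  clustering at distance 1 − |r| to drop near-duplicate covariates, then
  variance-inflation filtering (VIFⱼ = 1/(1 − Rⱼ²), threshold 5).
- **Spatially varying-coefficient regression**: GWR (local WLS with a
  Gaussian kernel w = exp(−(d/b)²), adaptive or fixed bandwidth, AICc
  bandwidth selection by golden-section search) and multiscale GWR fitted
  by backfitting with a separate AICc-optimal bandwidth per term,
  hat-matrix diagnostics (ENP, sigma, AICc, R²), and regional coefficient
  summaries.
- **A synthetic city-panel generator** with Gaussian-random-field
  covariates and known coefficient surfaces (constant / gradient /
  sinusoid), so every stage is testable against ground truth without any
  external data.

## Worked example

```r
library(spatdrivers)

# a 75-city panel (three contiguous groups, 5 signal + 4 nuisance
# covariates, 4 annual slices) with known coefficient surfaces
gen <- generate_panel(synthetic_spec(seed = 42))
panel <- gen$panel

# global spatial autocorrelation of the 2015 field
p15 <- panel_slice(panel, "2015")
global_moran(p15$y_resp, gen$weights)
#> Moran's I = 0.2057  (E[I] = -0.0135, Z = 3.588, p = 0.0003326, n = 75)

# screen drivers: cluster-drop, VIF, geodetector ranking
cfg <- run_config(out_dir = tempfile(), seed = 42)
screen <- run_driver_screen(panel, cfg, gen$polygons)
head(screen$factor_table, 3)
#>   variable         q            p
#> 1      X15 0.7153279 4.345939e-10
#> 2       X3 0.6599643 6.887206e-10
#> 3      X13 0.6188063 5.736918e-10
screen$selected
#> [1] "X15" "X3"  "X13" "X7"  "X5"

# GWR vs multiscale GWR on the selected drivers
sl <- city_panel(as.data.frame(p15), screen$selected)
g <- fit_gwr(sl, standardize = TRUE)
m <- fit_mgwr(sl)
compare_models(g, m)[c(1, 4, 5), ]
#>              index          GWR         MGWR
#> 1 Residual Squares    0.2900702    0.1951767
#> 4             AICc -126.0647171 -167.3694268
#> 5               R2    0.9960801    0.9973625
```

The Moran Z of 3.6 says the 2015 concentration field is far more
spatially clustered than chance; the q ranking orders covariates by the
share of spatial variance their stratification explains (here the five
planted signal covariates outrank the nuisance ones); and the comparison
table shows the multiscale fit dominating single-bandwidth GWR (lower
residual squares and AICc, higher R²), because each coefficient surface
gets a bandwidth matched to its own spatial scale.

`run_all(cfg)` executes the whole chain and writes every table (Moran
rows per group and time aggregation, LISA labels, VIF, factor/ecological/
interaction detectors, model comparison, bandwidth/ENP, regional mean
coefficients) as CSV with a JSON sidecar; a thin command-line wrapper is
in `inst/scripts/run_pipeline.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete pipeline on the built-in synthetic panel from the
given seed (all randomness flows from it) and writes the acceptance JSON.
The methodology's published tables derive from undistributed monitoring
and yearbook data, so correctness here is property-based: closed forms,
brute-force oracle equivalence, null calibration, parameter recovery and
pipeline determinism, all enforced in `tests/testthat/test-acceptance.R`.

## Documentation

The methods vignette (`vignettes/driving-forces.Rmd`) describes the
statistical model behind every stage, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and the
package's numerical choices.
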