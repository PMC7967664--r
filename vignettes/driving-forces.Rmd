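---
title: "Driving-force analysis of areal pollutant fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driving-force analysis of areal pollutant fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatdrivers)
```

`spatdrivers` operationalizes the analysis chain used in regional
air-quality studies of areal pollutant concentrations (the motivating case
is city-level PM2.5 in µg/m³): exploratory spatial autocorrelation,
stratified-heterogeneity detection, collinearity screening, and spatially
varying-coefficient regression. This vignette is the package's account of
the statistics it implements, the defaults it chooses where the underlying
methodology leaves them open, and the limits of what its tests establish.

## 1. Data model

The central container is the *city panel*: one row per areal unit and time
period, with planar centroid coordinates in kilometres (inputs in
geographic coordinates must be projected first; an equal-area projection
is recommended), a response concentration, named covariate columns, and
optional group (agglomeration) and time labels. Station-level records can
be aggregated into the panel with `aggregate_series()`, which works
stepwise — hours to days, days to months, months to seasons or years — and
reports a period only when the fraction of non-missing sub-periods reaches
a completeness threshold.

Three aggregation conventions matter and are configurable:

- **Completeness = 0.75 at every level.** Ambient-air standards require
  minimum data capture before a period mean is valid but the exact
  fraction varies by jurisdiction; 75% is a common, conservative choice.
- **Unit mean = unweighted mean of station means.** No population or area
  weighting; every monitoring station within a city counts equally.
- **Annual means average the 12 monthly means** rather than pooling hours,
  so months weigh equally regardless of data capture; likewise seasonal
  means average 3 monthly means. The seasons are meteorological
  (Mar–May spring, …), and December is assigned to the *following* year's
  winter, so winter 2016 = Dec 2015 + Jan 2016 + Feb 2016.

## 2. Spatial weights

Both Moran statistics use a binary, symmetric contiguity matrix W with
zero diagonal: `W[i, j] = 1` when units i and j are adjacent. W is *not*
row-standardized by default because the cross-product formulas below are
stated for binary weights; `row_standardize()` exists for users who want
the stochastic-matrix convention, and the two give different I values.

Adjacency can come from an explicit pair list or from unit polygons
(GeoJSON): queen contiguity links units sharing at least one boundary
point, rook requires a shared edge. Whether a study used queen or rook is
often unstated; the default is queen, which is the weaker (more connected)
assumption. Polygon matching is vertex-based after rounding, which is
exact for topologically clean layers (shared borders share vertices) and
is the only robust option without a computational-geometry stack; layers
with T-junctions should be cleaned upstream or supplied as a pair list.

Real study areas contain true islands (coastal island cities). Undefined
neighbourhoods make local statistics undefined, so by request
(`repair = TRUE`, and always in the pipeline) islands are linked to their
nearest unit by centroid distance, symmetrically, and the repair is
recorded on the object.

## 3. Moran statistics

Global Moran's I is the binary-weight cross-product statistic; its
expectation under the null is E[I] = −1/(n−1) and its variance is computed
under the randomization assumption by default (normality optional — the
choice is rarely stated in applied papers; randomization conditions on
the observed values and is the safer default). The standard score is
Z = (I − E[I]) / √Var(I) with a two-sided normal p. I can fall slightly
outside [−1, 1] for some weight matrices; the package warns rather than
errors, since the textbook range claim is only exact for row-standardized
W. A permutation version reports the pseudo p-value
(1 + #{|I_perm − E[I]| ≥ |I_obs − E[I]|}) / (1 + n_perm), reproducible
from a seed.

The local decomposition I_i uses the same deviations and the focal unit's
m_i neighbours, and satisfies Σᵢ I_i = S₀ · I exactly — a useful internal
consistency check that the tests assert. Because no analytic variance is
used, local significance comes from conditional permutation (hold the
focal value, permute the rest across neighbour positions; 999 draws by
default). Cluster labels are assigned by the quadrant of (own deviation,
spatial lag) at two tiers, |Z| ≥ 1.96 ("significant") and ≥ 2.58
("extremely significant"), with ties counting as significant; H–H is the
"hot zone", L–L the "cold zone".

## 4. Geodetector

The q-statistic measures the share of the response's variance explained
by a categorical stratification: q = 1 − Σₕ Nₕσₕ²/(Nσ²), with
*population* (divide-by-N) variances — the algebra that guarantees
q ∈ [0, 1] and q = 0 for a single stratum forces this choice.
Significance uses the noncentral-F approximation from the geodetector
literature (the convention of the standard software), with a seeded
permutation fallback.

Continuous covariates are discretized by natural breaks (Fisher–Jenks):
the k-class partition of sorted values minimizing the within-class sum of
squares, found by exact dynamic programming over the unique values
weighted by multiplicity. Eight classes is the default, a common choice
for detector analyses; the tests verify optimality against exhaustive
search on small instances.

The ecological detector asks whether two stratifications differ
significantly in explanatory power; with a common sample it reduces to
F = SSW_A/SSW_B on (N−1, N−1) degrees of freedom, tested two-sided so
the answer is symmetric in A and B. The interaction detector computes q
on the overlay (distinct pairs of strata) and classifies it against the
single-factor q's into the five standard classes (nonlinear-weaken,
uni-weaken, bi-enhance, independent, nonlinear-enhance), using a 1e-9
equality tolerance for "independent".

Detectors can run on unit values or on a regular grid sample of the unit
polygons (default 10 km spacing, the pipeline default); grid sampling
reweights units by area, which is how the source methodology operated.

## 5. Screening

Meteorological covariate sets typically contain near-duplicates (minimum /
mean / maximum temperature). Screening therefore proceeds in two stages,
in this order: (1) single-linkage ("minimum distance") hierarchical
clustering of covariates at distance 1 − |r| — the absolute value makes
strong negative correlates cluster too — cut at 0.1 by default, keeping
from each group the member most correlated with the response; then
(2) variance-inflation filtering, dropping the worst VIF iteratively
until all remaining values are ≤ 5. Doing the cluster-drop first prevents
a duplicated pair from masking the rest of the VIF table.

## 6. GWR and multiscale GWR

GWR fits a weighted least-squares regression at every unit with Gaussian
kernel weights w = exp(−(d/b)²) centred there. The bandwidth is adaptive
by default — b is each unit's distance to its k-th nearest unit, so k is
the tunable — because published bandwidth tables in this literature report
neighbour counts; a fixed-distance kernel is available. k is chosen by
golden-section search on the corrected AIC,

AICc = 2n·ln(σ̂) + n·ln(2π) + n(n + tr S)/(n − 2 − tr S), σ̂² = RSS/n,

over k ∈ [p+2, n] with integer rounding and ties broken toward the
smaller (more local) bandwidth. The search presamples a coarse
log-spaced grid before bracketing — single-term AICc profiles are
sometimes bimodal (a local basin and a global basin), and pure
golden-section can land in the wrong one — and falls back to a full grid
scan, with a warning, if the evaluated profile looks non-unimodal.
Diagnostics come from the assembled hat matrix: ENP = tr(S),
σ = √(RSS/(n − tr S)), R², adjusted R² with ENP as the parameter count,
and a local R² per unit under the focal kernel weights.

Multiscale GWR lets every term — the intercept included, matching the
published bandwidth tables that list one for it — carry its own bandwidth.
It is fitted by backfitting: terms are initialized from a GWR fit at its
single AICc-optimal bandwidth, then cycled over; each step forms the
term's partial residual, re-selects that term's bandwidth by AICc, and
re-smooths. Convergence uses the SOC-f score (root-mean-square change of
fitted values over their root mean square), tolerance 1e-5, at most 200
cycles. Per-term smoother matrices are propagated exactly through the
recursion R_j ← S_j(I − Σ_{l≠j} R_l), so per-term ENPs sum to the total
ENP to machine precision.

Two design points deserve emphasis:

- **Initialization matters.** With an OLS start all terms begin flat and
  the intercept — the most flexible term, able to absorb *any* smooth
  spatial field — grabs the spatial signal in the first cycle, which can
  stick the algorithm in a fixed point where a genuinely fine-scale
  coefficient is fitted as global. The GWR start gives every term
  locally-correct structure and resolves this; an OLS start remains
  available (`init = "ols"`) and is the default when bandwidths are
  forced.
- **Backfitting is not the joint local fit.** The backfitting fixed point
  solves per-term local normal equations with the *other terms evaluated
  at their own locations*; joint GWR solves all coefficients at the focal
  location simultaneously. The two coincide exactly only when the term
  smoothers are projections, i.e. in the flat-kernel (large-bandwidth)
  limit, where backfitting is Gauss–Seidel on the joint normal equations.
  At strongly local common bandwidths the estimators differ at the 1e-2
  level on the test fixtures — a property of the algorithm, not a bug —
  and the test suite asserts both the near-global equivalence and the
  finite-bandwidth difference.

Standardization: MGWR z-scores the response and covariates by default
(the convention of the reference software, making bandwidths and
coefficient magnitudes comparable across terms); GWR defaults to raw
scale. Model comparisons are made with both fitted under the same
standardization.

## 7. Synthetic data: what it emulates and what it does not

`synthetic_spec()` defines a rectangular lattice of square "cities"
(default 5 × 15 = 75 units at 50 km spacing — a typical inter-city
centroid distance — split into three contiguous groups of 17/31/27,
mirroring a three-agglomeration study region), covariates drawn as
unit-variance Gaussian random fields with exponential spatial covariance,
coefficient surfaces from the constant / gradient / sinusoid triad
standard in the multiscale-GWR simulation literature, and i.i.d. Gaussian
noise (default SD 0.5).

The default panel plants five signal covariates (named X3, X5, X7, X13,
X15, the shape of a screened driver set: enterprises, public vehicles,
green coverage, wind speed, precipitation), three nuisance covariates
carrying no effect, and one near-duplicate pair (r = 0.95, emulating
minimum vs mean temperature) that exists to exercise the cluster-drop
stage.

Two generator choices were made on statistical grounds and then frozen:

- **Signal covariates share a latent smooth field** (loading 0.75, range
  150 km). Real driver fields are strongly cross-correlated — economic
  activity, vehicles and industry covary, as do meteorological variables —
  and this correlation is what gives each driver a large *marginal*
  explanatory share. With fully independent covariates each of five
  signals can explain at most ~1/5 of the variance, which at 75 units is
  statistically indistinguishable from the q-statistic's chance floor
  ((L−1)/(N−1) ≈ 0.1 at L = 8, inflated further by spatial smoothness);
  no screening procedure could recover such a planted set reliably, so a
  generator without cross-correlation would misrepresent the kind of data
  the method is designed for. Nuisance covariates use rough (30 km)
  independent fields.
- **Recovery fixtures use spatially rough covariates.** When covariates
  are themselves smooth at the scale of the coefficient surfaces, the
  product β_j(s)·x_j(s) is a smooth field that the varying intercept can
  absorb — the varying-coefficient decomposition is then weakly
  identified, for any estimator. The multiscale-GWR simulation literature
  uses i.i.d. covariates for exactly this reason, and the 20 × 20
  parameter-recovery fixture follows it (range 30 km ≈ white at 50 km
  spacing).

What the generator does **not** emulate: real administrative geometries
(units are squares), measurement error and missingness patterns of
station networks, temporal autocorrelation (time slices are independent
redraws), non-Gaussian covariate distributions (yearbook counts are
heavy-tailed), and monetary or demographic semantics. A green test suite
therefore establishes that the statistics and the pipeline are computed
correctly and behave as theory predicts on well-specified inputs — not
that the scientific conclusions of any particular applied study are
correct.

## 8. Numerical choices and degenerate inputs

- Constant response or covariate fields error early with a named column.
- Duplicate coordinates in regression are separated by a deterministic
  micro-jitter (10⁻⁹ of the coordinate range) with a warning.
- A singular local design (bandwidth too small) errors with advice to
  enlarge the bandwidth rather than silently regularizing.
- Zero-neighbour units get undefined local Moran values and an NS label,
  with a warning, unless island repair is on.
- |Z| threshold ties count as significant (≥, not >).
- Natural breaks require at least k distinct values; saturated
  classifications (k = number of distinct values) give zero within-class
  variance.
- All permutation procedures take explicit seeds; the pipeline derives
  per-stage seeds deterministically from the single run seed, so two runs
  from one configuration are file-identical.

## 9. Known limitations

Planar distances only (pre-project geographic inputs); Gaussian kernel
only (no bisquare/exponential); no Monte-Carlo nonstationarity tests for
GWR coefficients; no spatiotemporal (GTWR) extension; the risk-detector
submodel of the geodetector family is out of scope. Polygon contiguity
assumes topologically clean boundaries. The hat-matrix bookkeeping in
MGWR stores n × n matrices per term, which is comfortable at panel sizes
typical of city-level studies (tens to hundreds of units) but would need
a different strategy at several thousand units.
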