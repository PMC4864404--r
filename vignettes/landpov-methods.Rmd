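---
title: "Methods: land-degradation accounting and the growth-poverty system"
author: "landpov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-degradation accounting and the growth-poverty system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landpov)
```

## The problem

Land degradation — a persistent decline in the productive capacity of
agricultural land — falls hardest on rural populations in low- and
middle-income countries. `landpov` implements a two-stage analysis of this
problem. Stage one is an accounting exercise: from gridded inputs it
classifies agricultural land as *degrading* (DAL) or *improving* (IAL),
splits each by market access into *accessible* and *remote*, and tabulates
how many rural people live on each class, by country and region, for two
epochs. Stage two is econometric: across countries, it asks whether the
spatial distribution of rural people over these land classes changes how
much income growth reduces poverty.

## Stage one: classification and accounting

### Inputs and data model

Seven mutually aligned grid layers drive the classification: a
net-primary-productivity (NPP) trend surface in gC/m²/yr, agricultural and
urban 0/1 extent masks, a travel-time-to-market surface in hours,
population counts per cell for both epochs, and an integer country-zone
map with a region lookup. Layers are plain matrices with georeferencing
metadata (`grid_layer`); the on-disk format is a self-describing CSV
raster. Row 1 is the northernmost row, cells are treated as equal-area
(no latitude correction — a documented limitation), and all layers are
brought onto the reference geometry by nearest-neighbour assignment,
which preserves mask and zone semantics and never interpolates
categorical values.

### Classification rules

A cell is classified only when it is agricultural and every needed layer
is valid there; otherwise it is excluded from all tabulations.

* **Trend**: degrading if the NPP change is strictly negative; improving
  if non-negative. An exactly-zero trend is improving — trend rasters
  contain exact zeros, so the boundary matters and is stated explicitly.
* **Remoteness**: a cell has market access if travel time to the nearest
  market city is strictly under `threshold_hours` (default 5 h);
  otherwise — including unreachable cells — it is remote. Exactly five
  hours is therefore remote. The threshold is configurable for
  sensitivity runs.

The four resulting classes partition the agricultural cells with complete
data; raising the threshold weakly shrinks the remote classes.

### Accounting

Rural cells are the complement of the urban extent (an extent rule, not a
density rule). Per country we sum rural population overall and on each
class, and express four shares as percentages of rural population: `d1`
(all DAL), `d2` (remote DAL), `i1` (all IAL), `i2` (remote IAL). Regional
and world rows recompute shares from summed populations — never as
averages of country shares — so every reported share is exactly its
population ratio. Countries with zero rural population get flagged,
undefined shares rather than division errors. Epoch changes are plain
percent changes with an undefined flag at zero baselines, and
density-change summaries report per-cell changes in persons/km² on DAL
and IAL cells.

Two printed header cells of the published degrading-land table disagree
with their own population columns (the developing and world share cells
appear transposed); the bundled reference table stores the values
recomputed from the population columns, which also match the published
in-text 2010 narrative.

## The synthetic landscape generator

Real inputs at global scale cannot be bundled, so the generator emulates
their structure at desk scale and makes every stage testable:

* spatially autocorrelated fields are white noise convolved with an
  isotropic Gaussian kernel (FFT, circular boundary), standardized to
  zero mean and unit variance; `smoothing_scale` is the kernel SD in
  cells;
* country zones are a nearest-seed partition; the agricultural mask
  thresholds a smoothed field at the `agri_fraction` quantile; the NPP
  trend is a second field shifted so the configured fraction of
  agricultural cells is negative (quantile shift, exact up to cell-count
  rounding) and scaled to a realistic ±tens of gC/m²/yr;
* one market city per country sits at the country's population-potential
  maximum; cells within a fixed radius are urban and are rescaled to hold
  `urban_pop_share` of the population; population decays away from cities
  on a log-normal surface and is normalized to `pop_total` exactly;
* travel time is the cost-distance to the nearest city over an
  8-neighbour lattice whose step cost is the mean of the two cells'
  hourly crossing costs (×√2 diagonally), computed with Dijkstra's
  algorithm;
* the second epoch multiplies population by `1 + pop_growth_2000_2010`
  (default 0.13, the published developing-country DAL growth rate) with
  mild multiplicative noise, renormalized to the grown total.

Defaults (64×64 cells, 6 countries, 40% agricultural extent, 45% of
agricultural cells degrading, 30% urban population share) were chosen
once as a qualitatively realistic miniature of the global inputs. What
the generator does **not** emulate: sensor noise and orbital artifacts,
realistic road networks, latitude-dependent cell areas, and coastlines.
Passing tests on these landscapes therefore validate the *accounting
machinery*, not any statement about the real rasters.

## Stage two: the growth-poverty system

### Spells and growth rates

For each country the longest spell between two comparable household
surveys inside the window (initial year 2000 or the soonest subsequent
year) is selected; both endpoints must use the same welfare indicator,
with ties broken by the earlier start and then by preferring consumption
over income (a convention of harmonized survey databases, adopted here
as a design choice). Growth rates are annualized log changes in percent
per year, `100·(ln x₁ − ln x₀)/years`, for both the $2.00/day headcount
rate `H` and survey mean income `μ`. A headcount of exactly zero cannot
be log-differenced; such countries are dropped for that variable rather
than erroring. Descriptive tables use the n−1 sample standard deviation.

### The structural model

The estimated two-equation system is

$$G:\quad g_j = \delta_0 + \delta_1\,\gamma(\mu_j) + \Lambda'W_j + \nu_j$$
$$P:\quad \gamma(H_j) = \beta_0 + \beta_1\,(1 \mp s_j/100)\,g_j
  \;[+\;\theta s_j] + \Gamma'Z_j + \varepsilon_j$$

with minus for degrading-land shares and plus for improving-land shares.
The share modifies the *poverty-reducing channel of growth* rather than
entering only directly; the optional direct term `θ·s` lets that
hypothesis be tested. Because `ν` and `ε` are correlated, the growth
index `g` is endogenous in `P`; the exogenous `W` variables (and their
interactions with the adjustment factor) are the instruments.

Estimators: OLS, two-stage least squares, SUR, and three-stage least
squares, all as explicit matrix implementations with classical/IV
covariances; 3SLS estimates the residual covariance from stage-1 2SLS
residuals with denominator *n* (no degrees-of-freedom correction) and
applies stacked GLS with instrument projection. In the documented
degenerate limits (diagonal residual covariance, common instruments)
3SLS collapses to per-equation 2SLS and SUR to OLS, which the tests
verify against independent matrix-formula oracles. Wald tests use the
asymptotic χ² reference without a small-sample F correction.

The total derivative of poverty growth with respect to income growth is
$\beta_1\delta_1(1 \mp s/100)$, so the **marginal impact** reported in
the schedules is $\beta_1\,\delta_1\,(1 \mp s/100)\,\bar\gamma(\mu)$ at
the sample mean income growth (3.36 %/yr in the reference sample). The
published schedule's footnote abbreviates this composite as
$\beta_1(1 \mp s/100)\gamma(\mu)$, but only the composite form
reproduces the printed cells; the package implements the composite.
Schedules are evaluated at the share's sample mean ± one SD (± half an
SD for `i2`, whose dispersion would otherwise push the lower point to
zero), clipped at zero and displayed at 0.1 precision with half-up
rounding (printed tables round halves up; banker's rounding would
misreproduce labels such as 48.2 and 13.5).

### The synthetic panel generator

`generate_panel` draws shares from normals at the reference sample
moments truncated (clamped) to [0, 100], income growth from
N(3.36, 3.52²), correlated structural errors, and builds `g` and `γ(H)`
from the system above with known coefficients; raw spell fields are
back-computed (`H₁ = H₀·exp(years·γ(H)/100)`, `H₀` uniform on [5, 95],
spell lengths uniform on 2–11 years) so that spell construction and
annualization round-trip to machine precision. Defaults `β₁ = −2.15`,
`δ₁ = 0.54` mirror the no-controls degrading-land column of the
reference estimates; `β₀ = −4.86`, `δ₀ = 0` place the structural means
at the reference descriptives. Note that clamping a N(27.11, 21.04²)
draw to [0, 100] truncates about 10% of its mass at zero and shifts the
realized moments (to ≈28.1 / 19.3); the moment tests therefore compare
sample moments against the truncated distribution's analytic moments,
not the nominal normal parameters.

The instrument set is made explicit in the generated data (the `W`
columns) rather than guessed from the published supplementary material,
whose instrument list is not printed; this is the minimal design that
gives the IV machinery genuine endogeneity to resolve.

## Numerical choices and degenerate inputs

* Missing cells are `NA` in memory; the nodata sentinel exists only on
  disk. `Inf` travel times (unreachable cells) are remote by definition.
* Nearest-neighbour alignment is idempotent; a warning is emitted if
  resampling changes a population layer's global sum.
* Rank-deficient designs raise an error naming the collinear columns;
  under-identified IV systems raise an identification error; a singular
  residual covariance suggests the SUR/2SLS fallback.
* Zero-variance share columns make the restriction test impossible and
  are rejected as input errors.
* Display rounding is half-up with a 1e-8 relative epsilon (IEEE doubles
  store decimal halves slightly low).

## Problem sizes

The bundled tests run landscapes at 24–128² cells and Monte-Carlo
studies of 200 replicates at 500 countries — sizes chosen so the full
suite completes in seconds while leaving every estimator property
(bias < 5%, CI coverage, test size and power) measurable with binomial
precision. The same generators scale to larger grids and samples by
configuration.

## Known limitations

* Uniform cell areas: population-per-cell accounting ignores the
  latitude dependence of cell area; real-raster work should pre-aggregate
  onto an equal-area grid.
* No reprojection between coordinate reference systems; single-band CSV
  rasters only.
* The estimation sample attrition of the reference analysis (83 survey
  countries vs 80 regression observations) follows an unstated rule and
  is not emulated.
* Classical (non-robust) covariances; no bootstrap or cluster inference.
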