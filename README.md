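# landpov

Tools for studying whether land degradation slows poverty reduction in
developing countries.

`landpov` is aimed at researchers working at the junction of geospatial
land accounting and cross-country poverty econometrics. It implements a
two-stage analysis:

1. **Accounting.** Gridded inputs — a net-primary-productivity (NPP)
   trend surface, agricultural and urban extent masks, a
   travel-time-to-market surface, per-cell population counts and a
   country-zone map — are overlaid to classify agricultural land as
   *degrading* (DAL: negative NPP change) or *improving* (IAL:
   non-negative change), each split into *accessible* (under five hours
   to a market city) and *remote*. Rural populations are tabulated on
   each class per country and region, yielding four shares of rural
   population: `d1` (all DAL), `d2` (remote DAL), `i1` (all IAL), `i2`
   (remote IAL).

2. **Econometrics.** A cross-country spell panel of household surveys
   gives annualized log growth rates of the $2/day headcount rate,
   γ(H), and of survey mean income, γ(μ). The two-equation system

   ```
   G:  g      = δ0 + δ1·γ(μ) + Λ'W + ν
   P:  γ(H)   = β0 + β1·(1 ∓ s/100)·g [+ θ·s] + Γ'Z + ε
   ```

   (− for DAL shares, + for IAL shares; `g` an endogenous growth index)
   is estimated by OLS, 2SLS, SUR and 3SLS, with Wald tests separating
   the direct channel (θ) from the indirect channel through growth. The
   implied marginal impact of growth on poverty,
   `β1·δ1·(1 ∓ s/100)·γ̄(μ)`, is evaluated on share schedules at the
   sample mean ± SD.

Synthetic generators for both stages (autocorrelated landscapes with
cost-distance travel times; structural panels with known coefficients
and cross-equation error correlation) make every step testable without
external data.

## Worked example

Run the whole pipeline — simulate a landscape, classify it, tabulate,
simulate a panel, fit the system, test restrictions, evaluate impacts —
from one configuration:

```r
library(landpov)
d <- file.path(tempdir(), "demo")
m <- run_pipeline(run_config(
  landscape = landscape_config(nrows = 48, ncols = 48, n_countries = 6),
  panel     = panel_config(n_countries = 120),
  output_dir = d, seed = 42))

read.csv(file.path(d, "region_table_2000.csv"))[
  , c("region", "rural_pop", "pop_DAL", "d1", "i1")]
#>       region rural_pop pop_DAL     d1       i1
#> 1        EAP     42261     0.0 0.0000  6.33765
#> ...
#> 7 Developing    700000 16990.1 2.4272 16.77439
#> 9      World    700000 16990.1 2.4272 16.77439

m$restriction_verdict
#> [1] "indirect-only"

read.csv(file.path(d, "impact_table.csv"))
#>   share_variable point share no_controls with_controls            range
#> 1             d1   low   7.6       -3.06         -3.05 -3.05% to -3.06%
#> 2             d1   mid  26.0       -2.45         -2.45 -2.45% to -2.45%
#> 3             d1  high  44.5       -1.84         -1.83 -1.83% to -1.84%
```

Reading the output: the tabulation says 2.4% of this synthetic world's
rural population lives on degrading agricultural land. The restriction
test supports the indirect-only channel (the generator's truth: the
share has no direct effect, θ = 0). The impact schedule says that at a
degrading-land share one SD *above* the mean (44.5%), income growth
cuts poverty by about 1.8%/yr, versus about 3.1%/yr at one SD *below*
— concentrating rural people on degrading land blunts the
poverty-reducing power of growth.

The generated `report.md` (`render_report(m)`) formats these tables and
appends a checklist that recomputes the bundled published reference
arithmetic (share recomputation, world totals, evaluation points,
impact schedule) with pass/fail marks.

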