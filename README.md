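# droughtimpact

Climate-change health impact assessment of drought and suicide, as an R
package. `droughtimpact` implements the full analysis chain used to ask
"how many suicides per year are attributable to drought, now and under
future rainfall scenarios?" for a panel of regions with monthly
rainfall, population and cause-of-death data:

1. **Drought indexing** — a modified Hutchinson Drought Severity Index
   (HDSI). Six-month rolling rainfall totals are expressed as
   calendar-month-conditioned percentiles over a rolling 30-year
   look-back window and rescaled so that the 1st, 50th and 99th
   percentiles map to scores of −4, 0 and +4. A month scoring ≤ −1 is
   in *mild drought*; the seventh consecutive mild month opens a *full
   drought*, which ends when the score rises above −1. The regression
   exposure is X = ln(1 + consecutive dry months).
2. **Exposure-response model** — a Poisson time-series GLM of monthly
   suicide counts O_ijkt with one linear drought slope per
   age (10–29, 30–49, 50+) × sex × rural/urban stratum, a natural cubic
   spline trend (df = 3) interacted with age × sex, a cyclic cubic
   seasonal spline (df = 4), region fixed effects, a temperature-anomaly
   term and offset ln(Pop_ijkt). Relative risks are reported per
   interquartile-range increase in X.
3. **Scenario projection** — future monthly rainfall per GCM × RCP by
   the delta-change method: percentage changes applied to the cycled
   observed 1986–2005 baseline climate, with drought exposure
   recomputed over the combined 1940–2099 series.
4. **Attribution** — attributable numbers per annum by stratum,
   AN = Σ over full-drought months of (1 − e^(−β·X)) × historical mean
   deaths for that region and calendar month, with empirical 95%
   confidence intervals from Monte Carlo draws of β ~ N(β̂, SE).

Because the real inputs (gridded rainfall, unit-record deaths) are
restricted, the package ships a seeded synthetic-data module that
emulates their statistical structure — seasonal gamma rainfall with
AR(1) persistence on normal scores, drought-coupled temperature
anomalies, census-interpolated populations, and Poisson counts drawn
from the exact generative inverse of the fitted model — so every stage
is testable end to end.

## Worked example

```r
library(droughtimpact)

cfg  <- sim_config(seed = 7)                  # 8 rural + 3 urban regions
rain <- generate_rainfall(cfg)                # monthly mm, 1940-2007
ex   <- drought_counter(score_series(rain))   # HDSI scores + drought state
temps <- generate_temperature(cfg, ex)
pops  <- population_panel(cfg)
sui   <- generate_suicides(ex, temps, pops, cfg)

urban <- setNames(vapply(cfg$regions, function(r) r$is_urban, logical(1)),
                  vapply(cfg$regions, function(r) r$region_id, character(1)))
fit <- fit_poisson(sui, ex, temps, urban)     # 1970-01 .. 2007-10
rr_per_iqr(fit, iqr = 1.07, "30-49", "male")$rr
#> [1] 1.125744
dispersion(fit)
#> [1] 1.013914
```

The printed relative risk is the fitted rural-male-30–49 risk ratio per
1.07-unit IQR increase in log drought duration for this seed (the
generating value is 1.14); the dispersion near 1 says the Poisson
variance assumption holds for the simulated counts.

A full run — simulation, indexing, fit, three scenarios, attribution
with Monte Carlo CIs, and summary tables — is one call:

```r
res <- run_pipeline(list(seed = 1, out_dir = "run1"))
res$tables$an          # AN per annum with 95% CI per stratum x scenario
res$tables$durations   # mean full-drought durations per region/scenario
```

## Command line

```sh
Rscript -e 'droughtimpact::drought_cli()' drought-index \
    --rain rain.csv --lookback-years 30 --out exposure.csv
```

Subcommands: `simulate`, `drought-index`, `project`, `run`.
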