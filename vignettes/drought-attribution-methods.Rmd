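---
title: "Methods: drought indexing, exposure-response modelling and attributable numbers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought indexing, exposure-response modelling and attributable numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtimpact)
```

This vignette is the package's own account of the science it
implements: the drought index and its accounting rules, the Poisson
exposure-response model, the delta-change scenario machinery, the
attributable-number calculation, and — because the real climate and
mortality inputs are restricted-access — what the synthetic-data
generator does and does not emulate. It states no empirical result
that the test suite or the acceptance script does not itself compute.

## 1. The drought index

The Hutchinson Drought Severity Index is a rainfall-only agricultural
drought indicator. For region $k$ and month $t$ the six-month rolling
total $T_{kt} = \sum_{s=t-5}^{t} R_{ks}$ is ranked against totals
ending in the *same calendar month* over a rolling 30-year look-back
window (the nominated year and the previous 29), so a dry January is
judged against other Januaries, and the notion of "normal" itself
drifts with the climate of living memory. The percentile $p$ is mapped
to a score by the anchor-constrained linear rescaling

$$\mathrm{score} = \frac{p - 50}{12.25}, \quad \text{clamped to } [-4, 4],$$

which sends the 1st, 50th and 99th percentiles to −4, 0 and +4
exactly. We use Hazen plotting positions $p = 100(r - 0.5)/n$ with
mid-ranks for ties: the convention is symmetric (a constant rainfall
series sits at $p = 50$, score 0, for every month) and never returns
the degenerate percentiles 0 or 100. The textbook alternative map
$8p/100 - 4$ gives −3.92 at $p = 1$ and is rejected because it misses
the stated anchors.

Drought accounting is a small state machine: a month with score ≤ −1
(threshold inclusive) is in mild drought and increments a counter;
the counter resets the month the score rises above −1. Six consecutive
mild months are within normal variability; the seventh opens a *full
drought*, which persists until reset. Reported spell durations count
full-drought months, `n_mild_months − 6`; the spell table also carries
the raw mild-month run length since descriptive tables in this
literature are ambiguous about which convention they print.

The regression exposure is $X = \ln(1 + \text{counter})$. Drought
durations enter the model on the log scale and the $+1$ keeps $X = 0$
outside drought; no zero-handling rule is stated in the source
literature, and this is the standard choice. $X$ enters the regression
for *all* months; attribution, by contrast, sums only months in full
drought (drought index > 6).

Two properties pin down the implementation and are enforced in the
tests: scores are invariant to multiplying an entire rainfall series
by any positive constant (only ranks matter), and the streaming
implementation agrees exactly, month by month, with a brute-force
sort-and-rank oracle.

## 2. The exposure-response model

Monthly suicide counts $O_{ijkt}$ for age group $i$ (10–29, 30–49,
50+), sex $j$ and region $k$ are modelled as Poisson with log link:

$$\log E[O_{ijkt}] = \beta_{ij r}\, X_{kt}
 + \alpha_k + f_{ij}(t) + g(m_t) + \gamma\, \mathrm{tmax}_{kt}
 + \log \mathrm{Pop}_{ijkt},$$

with one linear drought slope per age × sex × rural/urban stratum
(12 slopes, parameterized as separate columns so each is directly
readable), region fixed effects $\alpha_k$, a natural cubic spline
trend with df = 3 interacted with age × sex, a cyclic cubic seasonal
spline with df = 4 (continuous value and derivatives across the
December–January wrap), a shared temperature-anomaly coefficient and a
population offset. Spline degrees of freedom are fixed at the final
reported model's values rather than chosen by generalized
cross-validation; the same fitting interface accepts other df values
and a sine/cosine seasonal variant for sensitivity refits, which is
what the original smoothness-selection step was ultimately used to
justify.

Estimation is maximum likelihood by iteratively reweighted least
squares (deviance tolerance $10^{-8}$, at most 100 iterations, crude
overall rate as starting intercept). The fit reports the full
coefficient covariance $(X^\top W X)^{-1}$; a Pearson $\chi^2/\mathrm{df}$
dispersion statistic near 1 supports the Poisson variance assumption.
Numerical notes: the design is checked for full column rank before
fitting; in very small synthetic worlds a stratum may have no deaths
in any drought month, in which case its slope separates to a large
negative value with a huge SE — expected behaviour at toy scale, and
harmless because such strata carry no attribution weight.

Relative risks are reported per interquartile-range increase in $X$:
$\mathrm{RR} = e^{\hat\beta \cdot \mathrm{IQR}}$ with Wald interval
$e^{(\hat\beta \pm 1.96\,\mathrm{SE})\cdot \mathrm{IQR}}$. The data
months over which the IQR is computed (all months, mild-drought
months, full-drought months) are not standardized in this literature,
so `exposure_iqr()` takes the choice as an explicit argument, the IQR
is always recomputed from the data at hand, and callers must report
the convention; the reference value 1.07 used in the acceptance
targets is passed explicitly.

## 3. Scenario projection

Future rainfall per GCM × RCP is built by the delta-change method:
monthly percentage changes relative to the 1986–2005 baseline climate,
ramping from 0 at 2006 to a per-region endpoint by 2099. The deltas
are applied to the *cycled observed baseline series* — projection year
$y$ replays baseline year $1986 + (y - 2006) \bmod 20$, scaled by
$(1 + \Delta/100)$ — not to the baseline climatological mean. This is
the single largest under-specification in published delta-change
drought work: scaling a flat climatology destroys interannual
variability and therefore *all* droughts, while cycling the observed
years preserves the variance structure the percentile index needs. The
cycle order is fixed, so scenarios are deterministic given history.
Scenario exposure is computed over the combined historical + projected
series, letting the 30-year percentile baseline roll forward into the
scenario era. The accounting window for scenario attributable numbers
is 2000–2099; deltas are defined from 2006, so 2000–2005 carry zero
delta — this reconciles the projection data convention with the
reporting period without inventing data.

One floating-point subtlety is worth recording: a zero-delta
projection year replays its baseline year *exactly*, so six-month
totals must be computed with a fixed summation order (windowed sums,
not cumulative-sum differences) for the replayed months to tie their
source months bitwise and receive identical mid-ranks. The scale-
invariance test fails without this.

## 4. Attributable numbers

For a stratum with drought slope $\beta$, historical mean deaths
$H_{km}$ (region $k$, calendar month $m$, averaged over the historical
years 1971–1999) and exposure series $X_{kt}$, the attributable number
over a period is

$$\mathrm{AN} = \frac{1}{\text{years}} \sum_{\substack{k,t \text{ in full} \\ \text{drought}}} \left(1 - e^{-\beta X_{kt}}\right) H_{km_t},$$

per annum, dividing by all calendar years in the period including
drought-free ones. The attributable fraction $1 - e^{-\beta X}$ is
bounded by 1, so a month can never contribute more than its historical
mean; negative $\beta$ gives negative AN (protective strata, as
reported for rural women). AN is additive over disjoint regions and
periods and monotone in $\beta$ and $X$.

Uncertainty: $\beta^* \sim N(\hat\beta, \mathrm{SE})$ is drawn
independently per stratum (matching the published wording; a
joint-covariance mode was considered and not implemented because no
cross-stratum quantity in the outputs requires it — cross-stratum
contrasts pair draws instead), the AN is recomputed per draw, and the
95% interval is the empirical 2.5th/97.5th percentile. Point estimates
use $\hat\beta$ itself; the Monte Carlo median is reported alongside
because the published point-estimate convention is unstated. Scenario
percentage changes and male−female differences are computed on
*paired* draws (same draw index across scenarios and sexes), which is
what makes narrow difference intervals possible even when the two
marginal intervals are wide.

## 5. The synthetic world

The generator exists so that every downstream stage is exercisable
with no restricted data, and its defaults *are* the stated world of
the package's tests:

* **Geography** — 8 rural + 3 urban regions with annual rainfall,
  per-sex populations and male suicide rates at the magnitudes of the
  published 1971–1999 descriptive tables; populations split equally
  across the three age groups (per-age detail is not published).
  Female rates are male rates × 0.24, the overall female/male ratio,
  so baseline log rates decompose exactly into region + sex main
  effects. This is deliberate: the published tables show mild
  region-by-sex rate variation that the model's main-effects structure
  cannot represent, and carrying it into the generator induces a
  confounded drought-slope bias of up to −0.13 in small female strata
  (measured during development); the package's generator stays inside
  the span of the model it feeds, which is also what the
  generative-inverse contract requires.
* **Rainfall** — gamma marginals (shape 2, month-specific scale
  $\mu_m/\text{shape}$, $\mu_m$ = annual mean × monthly weight;
  uniform weights by default, as interior NSW rainfall has weak
  seasonality) with AR(1) persistence $\rho$ on normal-score anomalies
  mapped back through the gamma quantile function. Positivity and the
  configured monthly means are exact; persistence tunes dry-spell
  lengths. $\rho = 0.85$ was calibrated once, before any acceptance
  run, so that a stationary synthetic century reproduces the published
  drought accounting (≈ 7 full droughts per 29 years, mean full-phase
  duration ≈ 9–12 months, maxima ≈ 25); monthly rainfall
  autocorrelation this high is physically a stand-in for ENSO-driven
  interannual persistence that a monthly AR(1) cannot otherwise
  express. It was not revisited afterwards.
* **Temperature** — anomalies $N(0, 1)$ °C, optionally coupled to the
  drought counter with target correlation 0.3 (the published
  drought-temperature correlation magnitude).
* **Counts** — Poisson draws from exactly the model of §2: stratum
  intercepts from the baseline rates, the configured drought slopes,
  a linear trend (default 0), a seasonal cosine of amplitude 0.1
  *projected onto the df = 4 cyclic basis* so the generative season
  lies in the fitted span, a temperature coefficient (0.01/°C), and
  the population offset. Default drought slopes: rural male 30–49
  $\ln(1.14)/1.07$, rural female 30–49 $\ln(0.86)/1.07$ (implied by
  the published RRs per 1.07 IQR), rural male 10–29 $\ln(1.10)/1.07$
  (reported positive and significant but without a printed RR), rural
  female 50+ $\ln(0.95)/1.07$ (reported as a possible decrease), all
  other rural and all urban slopes 0.

What a green test does **not** establish: the generator has no spatial
correlation between regions, no ENSO-like low-frequency structure
beyond AR(1), no demographic change (populations are constant unless
censuses are supplied), no reporting artefacts in the counts, and the
female/male rate ratio is forced constant across regions. Parameter
recovery on this world validates the estimation machinery, not the
published effect estimates themselves, which rest on restricted data.

A note on finite-count bias: at the published population scale the
smallest female strata average ~0.1 deaths per region-month, and the
Poisson MLE's $O(1/\mathrm{information})$ bias is measurable there
(≈ −0.01 on slopes whose seed-to-seed SD is ≈ 0.04). A ×25 population
diagnostic during development collapsed all slope biases to < 0.004,
confirming the effect is the estimator's small-sample property rather
than misspecification. The strict per-stratum recovery criterion in
the acceptance suite (bias within $2\,\mathrm{SD}/\sqrt{50}$) sits at
roughly the same magnitude for those sparse strata, so individual
strata can sit on either side of it; the package reports the criterion
as specified rather than widening it.

## 6. Reproducibility

All randomness flows from one master seed through a per-stage string
hash (`derive_seed`), so any stage can be re-run bit-identically in
isolation; generators save and restore the caller's RNG state. Fixed
seeds give bit-identical Monte Carlo intervals. `run_pipeline()`
writes every stage artifact as CSV/JSON plus a manifest with the
config hash and derived seeds.
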