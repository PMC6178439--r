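---
title: "Forecasting the annual CO2 rise from ENSO and emissions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting the annual CO2 rise from ENSO and emissions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(co2cast)
```

## The model

Interannual variability in the growth of atmospheric CO₂ is dominated by
the El Niño–Southern Oscillation: warm (El Niño) conditions in the
equatorial Pacific suppress net carbon uptake by tropical land ecosystems,
so a larger share of anthropogenic emissions remains airborne. `co2cast`
packages the statistical forecast built on that relationship. The target
quantity is the **annual increment**

\[
\Delta \mathrm{CO}_2(i) = \overline{C}_i - \overline{C}_{i-1},
\]

the difference between the annual mean concentrations of successive
calendar years, modelled as

\[
\Delta \mathrm{CO}_2(i) = \alpha_1 + \alpha_2\,N(i) + \alpha_3\,\varepsilon(i-1) + e_i,
\qquad e_i \sim \mathcal{N}(0, \sigma^2),
\]

with:

* `N(i)` — the Niño 3.4 SST anomaly (°C relative to a 1961–1990
  climatology) averaged over the twelve months from 1 April of year
  *i − 1* to 31 March of year *i*. This window straddles the two calendar
  years whose means the increment differences, and correlates more
  strongly with the increment than the calendar-year mean does: ENSO
  events peak in boreal winter, and their imprint on tropical
  land–atmosphere fluxes (and hence on the concentration record) carries
  into the following spring.
* `ε(i−1)` — total anthropogenic emissions (fossil fuel plus land-use
  change, GtC) of the *previous* calendar year. Emissions are published
  per calendar year; using the lagged total keeps the regressor fully
  observable when a pre-season forecast is issued.
* `e_i` — a Gaussian residual absorbing non-ENSO climate variability.
  Residuals are treated as independent; no autocorrelation structure is
  modelled (a deliberate non-goal — the historical residuals show no
  structure strong enough to justify one at this record length, and an
  AR term would complicate the miss-probability calculus below).

The increment is distinct from the **in-year growth rate** (the change in
concentration across one calendar year, the convention used by annual
carbon-budget assessments). Both statistics are implemented
(`annual_increment`, `in_year_growth`); the in-year growth rate uses the
December-minus-December single-month convention, isolated behind one
function so alternative boundary conventions (`boundary_month`) can be
configured. The two definitions can disagree about which year holds a
record: an ENSO event spanning two calendar years spreads its signal over
two increments but can concentrate it in one in-year growth value.

### Calibration

`fit_increment_model()` estimates the coefficients by ordinary least
squares via `stats::lm` (QR decomposition, no explicit matrix inversion)
on design rows assembled by `build_design_rows()`. Rows with any missing
component — an incomplete CO₂ year under the strict gap policy, a window
month absent from the SST record, a missing emissions year — are dropped
with a message rather than an error, since the usable row set depends on
dataset vintages. A rank-deficient design (collinear predictors) is
reported explicitly. The residual spread is the sample (n − 1) standard
deviation of the OLS residuals.

Worked reproductions of published forecasts inject coefficients verbatim
with `increment_model()` instead: the exact historical row set behind a
published calibration is generally not recoverable (emissions datasets are
revised retroactively, and edge years may or may not have been usable), so
the package treats published coefficient tables as first-class inputs, and
records in the run provenance when an override bypassed calibration.

### Uncertainty

The forecast interval is ±2 standard deviations. By default the standard
deviation is the calibration residual spread (`two_sd = 2 * residual_sd`);
a fixed half-width can be supplied instead (`fixed_two_sd`) to reproduce
printed intervals whose derivation is not recoverable. The same half-width
is applied to the annual mean and to each monthly mean — a simplification,
since single-month values at one observatory carry additional local
variability, but the convention the downscaling method implies.

## Seasonal downscaling

The concentration record has a pronounced seasonal cycle (drawdown through
the Northern-Hemisphere growing season, release in winter; maximum around
May, minimum around September). The forecast annual mean is downscaled to
monthly means by adding **seasonal adjustment factors**: for each calendar
month, the mean offset of that month from its year's annual mean over a
reference period (`seasonal_factors`). Each year's twelve offsets sum to
zero by construction, so the factors do too, and the monthly forecasts
average back to the annual mean exactly.

This assumes the cycle's shape is stationary. The diagnostic
`seasonal_amplitude_trend()` checks the assumption: per-year peak-to-trough
amplitude regressed on year should give a slope indistinguishable from
zero. How many reference years define the factors is a required explicit
parameter (`seasonal_reference_years`) rather than a default — the choice
trades sampling noise against slow drift in the cycle — and published
factor tables can be injected directly (`seasonal_factors =`), which is
what exact reproductions of worked monthly values do.

## ENSO index construction

Observed SST products and seasonal forecasts are both consumed as
**ensembles** of monthly anomaly series. For a pre-season forecast the
April–March window is not yet fully observed, so `combine_obs_forecast()`
splices observed members (window months before a split date) with forecast
members (split date onward) and summarizes the per-realization window
means as mean ± 2 s.d. Two pairing schemes are provided, since the choice
is not dictated by the method: the default pairs members by index,
recycling the smaller ensemble (realization count = larger ensemble size);
the alternative takes the full cross product. With many members the two
give nearly identical central values and spreads; tests pin both against
brute-force enumeration. Baseline construction is out of scope: inputs are
anomalies already, though `to_anomalies()` converts an absolute series
given a supplied per-month climatology.

## Counterfactual attribution

The El Niño contribution to a year's rise is estimated by re-evaluating
the fitted model with the SST anomaly zeroed (`counterfactual_increment`,
i.e. N = 0) and differencing: `contribution = with − without`, reported
also as a percentage of the with-El-Niño increment, rounded to the nearest
integer percent (the raw ratio is retained in the result object). Under
the model the contribution is identically α₂·N — the tests verify this
symbolically — so the attribution inherits the regression's assumptions
rather than adding new ones.

The no-El-Niño *monthly* concentration is the counterfactual annual mean
plus the month's adjustment factor (`no_nino_monthly`). Its baseline — the
previous year's observed annual mean — is taken as unaffected by the
event, which is optimistic when the event was already strong in the
baseline year's later months; no correction is attempted, as any
correction would require the process-based modelling this package
deliberately avoids. A second, cruder estimate extrapolates the recent
trend linearly from the previous year's monthly value
(`trend_extrapolation`); it is biased low whenever the recent trend was
itself suppressed (e.g. by a run of La Niña conditions), which is exactly
the situation in which the counterfactual method is preferable.

## Forecast verification

`verify_interval()` scores an observation against a central ± 2 s.d.
range. The boundary is inclusive — a tie counts as a hit — and ties are
adjudicated with a small numerical margin (10⁻⁹, relative) so that values
equal to the bound at printed precision are not lost to floating-point
representation. `monthly_hit_count()` applies the same rule across the
twelve months.

A correct probabilistic forecast still misses sometimes. Under
independent Gaussian errors the per-year coverage of a ±2 s.d. interval is
`pnorm(2) − pnorm(−2)` ≈ 95.45% — computed from the error function, not
hard-coded 0.95, so the per-year miss rate is 4.55% before rounding — and
`miss_probability(k)` = 1 − coverage^k gives the chance of at least one
miss in k years: about 21% over 5 years, 37% over 10, and essentially
even odds over 15. In the long run a *good* forecast system should show
precisely this failure rate; the test suite checks the empirical miss
rate of ±2 s.d. intervals on 1000 simulated forecast years against it.

## The synthetic-data generator

`generator_config()` / `simulate_bundle()` generate complete input bundles
(monthly CO₂ record, SST anomaly ensembles, emissions table) with known
ground truth, so every stage — readers, windowing, calibration,
forecasting, attribution, verification — is testable end to end without
external downloads. The generator's defaults describe one fixed synthetic
study emulating the 1959–2016 observational situation:

* **ENSO index**: a stationary monthly AR(1) with φ = 0.92 and innovation
  s.d. 0.36 °C. The implied monthly s.d. is ≈ 0.92 °C and the April–March
  annual-mean s.d. ≈ 0.8 °C, so a ~57-year realization spans roughly
  −1.5 to +2.0 °C in annual means, like the observed index. AR(1) is the
  simplest process with ENSO-like persistence; it does *not* reproduce
  ENSO's seasonal phase-locking or skewness.
* **Emissions**: a quadratic through 2.5 GtC (1959), 8.4 GtC (1997) and
  11.1 GtC (2015) — the observed anchors, giving the historical
  1997→2015 rise of 2.7 GtC — with optional year spikes to emulate
  land-use (fire) emission spikes.
* **CO₂**: annual increments generated *exactly* by the increment
  equation with the published-era coefficients (−0.132, 0.415, 0.237)
  plus a Gaussian residual of s.d. 0.25 ppm, accumulated from 316 ppm and
  downscaled with a fixed zero-sum seasonal cycle (May maximum +3.00 ppm,
  September minimum −2.97 ppm, ≈ 6 ppm peak-to-trough). Noise enters at
  the increment level so the regression holds exactly in expectation; an
  optional monthly observation-noise term (default off) breaks that
  exactness deliberately.
* **Ensembles**: members are truth plus independent per-month Gaussian
  noise of 0.35 °C (10 observed, 42 forecast members; the forecast covers
  November onward). Averaging 12 such months gives a per-realization
  window s.d. of 0.35/√12 ≈ 0.10 °C, hence a combined 2 s.d. of ≈ 0.2 °C,
  matching the uncertainty quoted for the real combined product.

All randomness derives from one integer seed through R's default
Mersenne-Twister generator; separate fixed offsets give each generator its
own reproducible stream. Because the generator shares the model's
structure, passing tests demonstrate *internal* consistency (calibration
recovers known coefficients; attribution recovers the injected
contribution) — they cannot validate the regression's adequacy for the
real carbon cycle, where the residuals include volcanic years in which
the ENSO relationship is known to break down. Volcanic exclusion years
are therefore a configuration option (`excluded_years`) rather than a
default: the default calibration includes all years.

## Numerical choices and problem sizes

* Reported ppm and °C values are rounded to 2 decimals at the reporting
  layer only; all internal arithmetic is full precision. Attribution
  percentages are rounded to integers (R's round-half-to-even).
* Gap policy for annual means: strict by default (any missing month is an
  error naming the month); an optional policy interpolates a single
  missing interior month from its within-year neighbours.
* Sample (n − 1) standard deviations throughout; a single-member ensemble
  has spread 0.
* The test suite's Monte-Carlo checks use 500 replicates of a 56-year
  calibration (coefficient coverage), 300 replicates against the analytic
  OLS standard error, and 1000–2000 simulated forecast years (interval
  calibration); the full suite runs in a few seconds on one CPU.

## Limitations

The method is a two-predictor linear summary of a nonlinear, lagged
system. It cannot anticipate volcanic eruptions (which cool the tropics
and temporarily reverse the ENSO–CO₂ relationship), treats a fire-driven
land-use emissions spike as anthropogenic forcing rather than ENSO
response, assumes one observatory's record proxies the global background,
and offers no process-level decomposition of the land and ocean sinks.
Within those limits it is cheap, transparent, and — as the verification
machinery here quantifies — skilful enough that its misses should arrive
at a predictable rate.
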