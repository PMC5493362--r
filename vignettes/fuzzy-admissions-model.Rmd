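---
title: "A Mamdani fuzzy model for pollution-driven respiratory admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Mamdani fuzzy model for pollution-driven respiratory admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyair)
```

## The problem and the modelling idea

Short-term exposure to particulate matter (PM10), ozone (O3) and sulfur
dioxide (SO2), together with cold weather, raises daily hospital
admissions for asthma and pneumonia.  Experts can state this knowledge
compactly — "when the air is bad and it is cold, expect many admissions" —
but such statements are vague in exactly the way fuzzy set theory was
built for.  `fuzzyair` encodes them as a Mamdani fuzzy inference system:

1. **Fuzzifier** — each crisp exposure is mapped to degrees of membership
   in linguistic terms (`good`/`bad`) with piecewise-linear trapezoidal
   membership functions.
2. **Rule base** — IF–THEN rules join one term per input to one term of
   the output variable, the daily admission count.
3. **Inference** — each rule fires at the *minimum* of its antecedent
   degrees; its consequent set is truncated at that strength; truncated
   sets are aggregated by pointwise *maximum*.
4. **Defuzzifier** — the aggregated set is collapsed to a crisp
   prediction by its area centre (centroid).

The engine (`fuzzy_variable()`, `fuzzy_rule()`, `fuzzy_system()`,
`infer()`) is generic; `asthma_system()` instantiates the respiratory
application.

## The shipped model and its parameters

Four inputs with two terms each give a complete rule base of
$2^4 = 16$ rules, generated by a severity map on the number of `bad`
antecedents: 0 bad → `very_low`, 1 → `low`, 2 → `medium`, 3 → `high`,
4 → `very_high`.  The two boundary rules are therefore *all good → very
low admissions* and *all bad → very high admissions*, and the map is
required to be monotone so that worsening any input can never lower the
predicted severity.  Users may replace the map, or supply an explicit
rule list in the model configuration file, when expert knowledge
disagrees with the count-of-bad heuristic.

Membership breakpoints are tunable and default to values anchored in
regulatory guide values and the observed ranges of a mid-sized
industrial city (units µg/m³ for pollutants, °C for temperature):

| variable | universe | good | bad | anchor |
|---|---|---|---|---|
| `pm10` | [0, 120] | (0, 0, 25, 50) | (25, 50, 120, 120) | air quality degrades above ~50 µg/m³ |
| `o3` | [0, 200] | (0, 0, 80, 160) | (80, 160, 200, 200) | 160 µg/m³ hourly guide value |
| `so2` | [0, 30] | (0, 0, 10, 20) | (10, 20, 30, 30) | 20 µg/m³ daily guideline |
| `temp_apparent` | [0, 30] | (12, 18, 30, 30) | (0, 0, 12, 18) | cold is the adverse state |

The exact curve shapes used in the original expert elicitation are not
published numerically, so these defaults are documented approximations
that reproduce the qualitative geometry (left/right shoulders crossing at
mid-range); every breakpoint is overridable via `asthma_config()` or a
YAML/JSON configuration file.  The direction of the temperature terms
(cold = bad) follows winter-excess respiratory epidemiology and is
likewise configurable.

The output variable spans [0, 16] daily admissions with five overlapping
terms, `very_low` (0, 0, 2, 4) through `very_high` (12, 14, 16, 16).
Because the prediction is a centroid, it can never reach the universe
ends: fully saturated inputs give the centroids of the extreme terms,
$14/9 \approx 1.55$ and $16 - 14/9 \approx 14.45$:

```{r extremes}
sys <- asthma_system()
predict_day(sys, list(pm10 = 10, o3 = 30, so2 = 2, temp_apparent = 25))
predict_day(sys, list(pm10 = 100, o3 = 190, so2 = 28, temp_apparent = 2))
```

### Apparent temperature

When a record carries ambient temperature and relative humidity instead
of an apparent temperature, `apparent_temperature()` computes a
Steadman-type index: the Magnus dew point (constants 17.27 and 237.7 °C)
feeds $AT = -2.653 + 0.994\,T_a + 0.0153\,T_d^2$.  The formula is kept in
one small function precisely so an alternative convention can be swapped
in.  Two caveats: relative humidity of exactly 0% is rejected (the dew
point is undefined there), and the index is monotone increasing in
humidity only above roughly 4 °C — below that the dew point is negative
and its squared contribution grows again as humidity falls.  Both are
edge cases outside the physiological range the model targets.

## Numerical choices

* **Discretisation.** The output universe is sampled at 1001 evenly
  spaced points (configurable, minimum 101).  At this resolution the
  centroid differs from a $10^5$-point quadrature by well under 0.05
  admissions for random rule activations, and doubling the resolution
  moves predictions by less than 0.02.
* **Clamping.** Crisp inputs outside a variable's declared universe are
  clamped to it before fuzzification, so a pollution episode above the
  historical maximum degrades gracefully instead of erroring.
* **Degenerate aggregation.** If no rule fires (possible only with
  non-covering terms), inference raises an explicit error rather than
  inventing a default; `fuzzy_variable()` enforces term coverage at
  construction, so the shipped model cannot reach this state.
* **Implication and aggregation** are truncation (min) and pointwise max
  — the classical Mamdani pair.  No product/sum variants, rule weights,
  hedges or alternative defuzzifiers are offered; the centroid is unique
  whenever any degree is positive, so no tie-breaking is needed.

## Validation methodology

`validate_predictions()` mirrors how such models are evaluated in
air-pollution time-series work.  Exposure leads outcome: the prediction
on day $t$ is paired with admissions on day $t + \ell$ for lags
$\ell = 0, 1, 2$; pairs with a missing member are dropped and counted.
Per lag it reports the Pearson correlation (two-sided $p$ from the $t$
distribution, $n-2$ df; no multiple-testing correction) and the ROC AUC
of the predictions against dichotomized admissions, with a
Hanley–McNeil 95% interval

$$SE^2 = \frac{A(1-A) + (n_1-1)(Q_1 - A^2) + (n_0-1)(Q_2 - A^2)}{n_1 n_0},
\quad Q_1 = \frac{A}{2-A},\; Q_2 = \frac{2A^2}{1+A}.$$

The AUC is the Mann–Whitney estimator computed from midranks, so ties
count one half; the test suite checks it exactly against brute-force
concordant-pair counting and against an independent ROC implementation.
The dichotomization threshold defaults to 2 (a positive day has more
than 2 admissions) and is exposed as a flag, because the convention of
treating "up to 2" admissions as the negative class is a reporting
choice, not a property of the method.  The Hanley–McNeil interval was
preferred over DeLong for its closed symmetric form; DeLong would be a
reasonable later addition.

## What the synthetic generator emulates — and what it does not

`generator_spec()` describes a synthetic year shaped like the 2007 daily
series of a mid-sized Brazilian industrial city: pollutant marginals
with mean/SD/min/max of PM10 (26.0, 11.3, 8.0, 89.0), O3 (91.0, 67.9,
17.0, 162.0) and SO2 (3.8, 3.3, 0.9, 27.0) µg/m³, a mean daily admission
count of 4.9 capped at the observed maximum of 16, and a planted
lag-specific pollutant→admissions association (default: +0.3 log-rate
per SD of PM10 at lag 1).

* Pollutants follow a stationary Gaussian AR(1) scaled to the target
  mean/SD and clamped to the observed min/max.  A truncated Gaussian was
  chosen over a lognormal because only mean/SD/min/max are known; no
  skew is assumed.  The AR(1) coefficient defaults to $\rho = 0.5$, a
  typical day-to-day persistence of urban pollutant levels.
* Ambient temperature (mean 18 °C, SD 2.5) and relative humidity (mean
  75%, SD 10) are generated the same way and the apparent temperature is
  *derived* from them, landing near the observed 17.9 °C mean.  The
  published SD of 0.9 °C for apparent temperature is internally
  inconsistent with its 5.7–20.2 °C range, so the generator honours the
  mean and range and lets the SD float.
* Admissions are Poisson with log rate
  $\beta_0 + \sum_p \sum_\ell \beta_{p,\ell}\, z_{p,t-\ell}$, where $z$
  standardizes each pollutant by the spec's own mean/SD (so each $\beta$
  is per-SD); lagged values before the series start contribute zero.

Not emulated: seasonality, day-of-week structure, overdispersion beyond
Poisson, and correlation *between* pollutants.  Passing tests on this
generator therefore demonstrate that the pipeline is correct and
calibrated — not that the default membership functions are optimal for
any real city; fitting real data still requires expert re-elicitation of
the breakpoints.

### Design of the lag-recovery experiment

The association-recovery experiment plants $\beta_{PM10,lag1} = 0.3$ at
$n = 365$ and asks whether the full pipeline (simulate → predict →
validate) ranks lag 1 highest by AUC in at least 45 of 50 replicates,
and whether with all $\beta = 0$ the mean AUC stays in [0.45, 0.55].
This experiment is run with serially independent exposures
($\rho = 0$): autocorrelated exposures transmit a single-lag association
into the neighbouring lags (exposure on day $t$ predicts exposure on day
$t\pm1$ and hence their outcomes), so with $\rho = 0.5$ lag attribution
is intrinsically blurred — a property of the data-generating process,
not of the pipeline under test.  The realistic default $\rho = 0.5$ is
kept for general fixtures.

Problem sizes throughout (365-day series, 50 replicates per experiment,
$10^4$ random inputs for the boundedness check, $10^5$-point quadrature
oracle) were chosen so each experiment has comfortable statistical
resolution while a full run of the suite stays fast on a laptop.

## Known limitations

* Membership breakpoints are documented approximations to an unpublished
  expert elicitation; predictions are interpretable but not calibrated
  against any real registry.
* The model is cross-sectional per day: no carry-over of predictions
  across days beyond the validation lags.
* Only the three modelled pollutants are supported (no CO or NOx), and
  only conjunctive (AND) rules.
* The Pearson/ROC validation treats days as exchangeable; serial
  correlation in real admission series will make nominal $p$-values
  optimistic.
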