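---
title: "Greenhouse microclimate suitability analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greenhouse microclimate suitability analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microclim)
```

`microclim` characterises the internal climate of a low-tech (passively
ventilated, unheated) greenhouse over a crop cycle from high-frequency
temperature/relative-humidity logs. This vignette explains the models the
package implements, the parameters that matter, the synthetic data it
tests itself on, and the design decisions taken where the methodology
left genuine freedom.

## Psychrometrics

Saturation vapor pressure follows the Tetens-type exponential

$$\mathrm{SVP}(T) = 0.6108 \cdot 2.7183^{\,17.27\,T/(T+237.3)} \quad [\mathrm{kPa}],$$

with actual vapor pressure $\mathrm{AVP} = \mathrm{SVP}\cdot RH/100$ and
$\mathrm{VPD} = \mathrm{SVP} - \mathrm{AVP}$. Two details are deliberate:

* The exponential base defaults to the four-decimal constant 2.7183 as
  commonly typeset in the horticultural literature rather than $e$; a
  property test pins the relative difference below $10^{-4}$ over
  0–50 °C, and `base = exp(1)` selects the exact form.
* Classification uses $|\mathrm{VPD}|$. With RH validated to $[0, 100]$
  the deficit is nonnegative and this is a no-op, but it makes the
  classifier robust to sign conventions in external inputs.

No alternative psychrometric formulations (Magnus variants, dew point,
wet bulb) are in scope.

## Suitability classification

A threshold table assigns each (stage, period, variable) combination a
closed optimal interval $[o_l, o_h]$ and outer critical cuts $c_l, c_h$.
The suboptimal band is implied: $[c_l, o_l)$ and $(o_h, c_h]$. Published
range tables of this kind contain typographic gaps (an optimal bound of
28 followed by a suboptimal bound of 28.1); closing the suboptimal band
up to the optimal bound — open toward optimal, closed at the critical
cut — makes the three categories a measurable partition of the real
line, which a 10,000-probe property test asserts. A value of 28.05 under
a 20–28 optimal / 28.1–34 suboptimal rule is therefore suboptimal-high.

The phenology calendar maps dates to stages through days after
transplant (DAT). The packaged tomato calendar uses the printed stage
windows (vegetative 0–50, reproductive 51–109, harvest 110–190 DAT) and
defines each stage's duration as the difference between consecutive
stage end-DATs, giving 50, 59 and 81 days and a 190-day cycle — the only
convention that reproduces all printed durations simultaneously, since
the printed DAT ranges and calendar dates are mutually inconsistent by
one day.

The day/night boundary is 06:00–18:00 local, half-open (`[start, end)`),
configurable. The split is not part of the published methodology; a
12-hour split is the natural choice for an equatorial site with
near-constant photoperiod.

Two aggregation views are provided, because the published tables do not
state which was used:

* **composite** (default): a record's category is the *worst* across T,
  RH and VPD (critical > suboptimal > optimal) — an integrated
  microclimate reading;
* **per-variable**: each variable separately, which is also what the
  critical-driver decomposition (share of time critically *low* vs
  *high* per variable) builds on.

Only the stage-average arithmetic — each sensor × period "average" row is
the unweighted mean of its three stage values — is treated as ground
truth; the acceptance suite verifies it against all printed average
cells. "Percentage of hours" is computed as record counts over
non-missing records; missing records never enter denominators, and empty
cells report `n_records = 0` with missing percentages, never zeros.

## Daily microclimate status

Per day and variable, the percentage of (non-missing) records in each
category gives nine predictors. The daily status follows the majority
rule: if at least two variables spent more than 50% of the day in the
same category, that category is assigned. The rule is silent when no
category reaches two votes; the package then assigns the category with
the largest mean share across the three variables, breaking exact ties
toward severity (critical > suboptimal > optimal), and flags the day
with `rule_satisfied = FALSE` so fallback days are auditable. Days with
a fully missing variable are excluded and logged.

## Classification trees under temporal validation

The tree learner is authored in full rather than delegated, because its
exact conventions (tie-breaks, pruning, fold construction) are the point:

* **Growth**: greedy binary splits minimising size-weighted child Gini
  impurity (classification) or child SSE (regression); candidate
  thresholds are midpoints between consecutive distinct feature values;
  ties break to the lowest feature index, then the lowest threshold;
  leaves predict the majority class with the first declared level
  winning ties. Defaults `min_split = 20`, `min_leaf = 7`,
  `max_depth = 30` mirror conventional CART practice. Root splits are
  verified against an exhaustive-search oracle on dozens of random tiny
  datasets, and whole-tree predictions against an established CART
  implementation (test-only).
* **Cost-complexity pruning**: weakest-link collapse by
  $g(t) = (R(t)-R(T_t))/(|T_t|-1)$ with resubstitution
  misclassification risk; `cp` is normalised by the root-as-leaf risk
  (relative-error convention, root error = 1) so grids are scale-free.
  Paths are tested for nestedness and strictly increasing alpha.
* **Rolling-origin cross-validation**: expanding training windows
  starting at the first row; after an initial window of 50% of the rows,
  the remainder is partitioned into `k = 5` near-equal contiguous
  validation blocks (both configurable — the methodology names neither
  value). Non-monotone timestamps raise a warning rather than being
  silently reordered.
* **1-SE rule**: the largest cp whose mean CV error is within one
  standard error of the minimum.
* **Temporal holdout**: the last `ceiling(0.30 n)` days, never shuffled.
* **Metrics**: accuracy, balanced accuracy (mean recall over classes
  present in the truth), macro F1 (classes present in the truth;
  an undefined per-class F1 counts as 0), and Cohen's κ (reported
  missing, with a warning, when expected agreement is 1).

No published numeric tree performance exists to compare against, so the
tree stack is validated by properties, including an end-to-end recovery
test: on 400 synthetic days whose status follows a planted two-rule
structure (critical iff the critical-RH share exceeds 50% or the
critical-VPD share exceeds 60%), the selected tree must reach holdout
balanced accuracy ≥ 0.9 and may only use the two planted drivers.

## Gap imputation

Sensor gaps are filled missForest-style: initialise missing entries with
column means; revisit variables in order of increasing missingness,
regressing each on the co-observed climate variable plus calendar/time
predictors (DAT, day of year, sin/cos-encoded clock hour, day/night
indicator, stage code) with a bagged ensemble of the package's
regression trees (defaults: 100 trees, bootstrap resampling,
`mtry = floor(sqrt(p))`, at most 10 iterations); stop when the summed
out-of-bag NRMSE stops improving, returning the previous iteration's
values. Conventions worth pinning:

* NRMSE uses the *population* variance of the truth in its denominator,
  so predicting the mean everywhere scores exactly 1; this is asserted
  in a unit test.
* Observed values are never altered (asserted cell by cell), runs are
  fully seed-determined, and a variable ≥ 50% missing is a contract
  violation, not a degraded fit.
* Each sensor is imputed independently with within-sensor predictors —
  the reading of "independently for each dataset" adopted here — which
  also keeps a failed sensor from contaminating its neighbours.

On simulated data with smooth diurnal structure and ≤ 5% missingness the
imputer must beat mean imputation and stay below 0.5 NRMSE against the
known truth for both variables.

## The synthetic generator

`simulate_greenhouse()` defines the study conditions the package tests
itself under: four quadrant sensors plus one external reference, 190
days at 5-minute resolution (54,720 records per sensor), with

* an asymmetric diurnal temperature curve (minimum 06:00, maximum 14:00;
  8-h rise, 16-h fall) whose day/night period means are solved exactly
  against the sampling grid, per stage — defaults are calibrated once so
  the realised stage means land on the published descriptive means
  (e.g. eastern-quadrant vegetative mean 20.3 °C);
* RH following its stage day/night targets in anti-phase modulation
  (pre-dawn peak), clipped to $[0, 100]$ — a continuous sinusoid was
  rejected because the large day/night RH gap would push the nocturnal
  curve far above 100% and clipping would bias the means;
* additive per-quadrant offsets sized to the published between-sensor
  spread, per-record Gaussian noise, and an AR(1) day-level drift
  ($\phi = 0.7$) giving realistic day-to-day persistence;
* external series with smaller amplitude and noise (outside air varies
  less than the covered volume) and day/night means set so the
  internal-minus-external contrast is larger by day than by night;
* MCAR missingness as geometric-length gaps (singletons arise from the
  geometric mass at 1) at the published per-sensor rates, 0.7–2.9%.

What it does **not** emulate: radiative/energy-balance physics,
ventilation aerodynamics, canopy feedback on sensor exposure, weather
fronts, sensor drift/bias, or missingness that depends on the weather
itself (outage mechanisms are unknown, so MCAR is the defensible
default). Passing tests therefore demonstrate correctness of the
*computations* under realistic statistical structure — not that the
generator is a climate model.

## Problem sizes and runtime

The test suite runs one full 190-day simulation (shared across test
files), imputation exercises on 4–6-day series with 10–15 trees, CV and
pruning on a few hundred rows, and the 400-day planted-rule recovery;
the whole suite completes in well under a minute on one core. Production
imputation with 100 trees on a full cycle is the one genuinely heavy
step; `run_pipeline()` therefore defaults to 25 trees and exposes the
full setting.

## Known limitations

* Daily external weather can only be compared against internal records
  through proxies (daily max for daytime, daily min for nighttime);
  record-level comparison requires the external 5-minute series.
* The economics module reproduces printed totals and derived ratios; it
  does not model prices, inflation or cost structure.
* Yield per plant uses the exact area conversion (1 ha = 10,000 m²);
  published per-plant figures rounded from unknown intermediate
  precision may differ in the last digit.
* The stage-average ratio of optimal to critical time quoted in some
  summaries of this methodology is not recoverable from the published
  average rows by any simple arithmetic; the package does not attempt
  it.
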