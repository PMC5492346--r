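---
title: "Methods: WBGT estimation, heat-event rules, and exposure-limit classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WBGT estimation, heat-event rules, and exposure-limit classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatstrain)
```

`heatstrain` evaluates occupational heat exposure for outdoor-worker case
series. This vignette documents the model choices, the tunable parameters
and their defaults, what the synthetic generators do and do not emulate,
and the numerical decisions — in particular every place where the
underlying definitions were open and the package had to choose.

## WBGT estimation from Ta and RH

Direct WBGT measurement needs a natural wet-bulb and a globe thermometer;
weather stations report neither. The package estimates WBGT in two steps
from the dry-bulb temperature Ta (°C) and relative humidity RH (%):
a closed-form wet-bulb approximation (the Stull-style empirical fit)
followed by a quadratic regression of outdoor WBGT on (Tw, Ta). Both
formulas are implemented literally as published:

* All `atan` terms operate in **radians**. The published formula block does
  not state the angular unit; radians reproduce the fit's reference
  behaviour (Tw ≈ 13.70 °C at Ta = 20 °C, RH = 50 %) while degrees do not,
  so radians is the only defensible reading.
* The `atan(Ta + RH)` term adds quantities with different units. That is
  how the empirical fit was constructed, so it is implemented as printed,
  not "corrected".
* No rounding happens inside the computation; 2-decimal presentation
  rounding belongs to serialization only.

```{r}
stull_wet_bulb(20, 50)
park_wbgt(30, 70)
```

**Validity envelope.** The wet-bulb fit was calibrated for roughly
RH ∈ [5, 99] % and Ta ∈ [−20, 50] °C. Outside that envelope the estimate is
still computed but carries `valid = FALSE`. Flagging instead of dropping or
clamping matters downstream: daily WBGT maxima take the max over *valid*
hours only, and a day with no valid hour reports `NA` rather than a number
built from extrapolated inputs. Within the envelope the estimate is
strictly below Ta whenever RH < 99 (positive wet-bulb depression) and
non-decreasing in both Ta and RH; the test suite checks both properties on
a Ta × RH grid and checks agreement with an independently coded
transcription of the formulas at 1000 random envelope points to 10⁻⁹ °C.

## Daily aggregation and the night window

Hourly series aggregate to calendar-day summaries: `tmax` (daily maximum
dry-bulb), `night_tmin` (minimum over the night window) and `wbgt_max`
(maximum valid estimated WBGT). Two asymmetries are deliberate:

* `tmax` uses whatever hours exist — a maximum is robust to gaps.
* `night_tmin` requires at least 75 % of the nominal night-window hours;
  otherwise it is `NA` (*indeterminate*). A minimum over a fragment of the
  night would be biased warm, silently producing false tropical nights.

The **night window** defaults to 18:00 (previous calendar day) through
09:00 (current day), 16 nominal hours. "Nighttime" has no standard
definition in the event rules this package implements, so the window is a
declared, configurable choice; it spans the civil evening-to-morning period
during which sleep happens, which is what the tropical-night flag proxies.
The flag attaches to the *morning's* date, so "illness onset after a
tropical night" tests the night immediately preceding the onset day. The
first day of any series is consequently indeterminate — its evening hours
were never observed.

## Event rules

* **Heat wave**: a maximal run of ≥ `min_run` (default 2) consecutive
  calendar days with `tmax` ≥ `threshold` (default 33 °C, the Korean
  advisory level; "33 °C or higher" is inclusive, so a 33.0 °C day
  qualifies). "Temperature" here is the daily maximum dry-bulb, the
  standard advisory semantics. A missing calendar day, or a day with
  missing `tmax`, breaks a run: absent weather is never assumed hot.
* **Tropical night**: `night_tmin` strictly above 25 °C ("above" is
  strict — a 25.0 °C minimum is not tropical). An indeterminate
  `night_tmin` yields an indeterminate flag, distinct from `FALSE`.

Episode detection is checked against a brute-force O(n²) window scanner on
random gapped 60-day sequences; raising the threshold can only shrink the
set of episode-days.

## Exposure limits

The limit engine maps (acclimatization status × metabolic-rate class) to a
WBGT screening limit and tests `wbgt_max ≥ limit` (inclusive, "equal to or
greater than"). The packaged default table follows the ISO 7243-style
reference values for continuous work in light work clothing:

```{r}
default_limit_table()
```

The exact thresholds used in the original case evaluation were not
printed; this table is the package's declared choice, and it is validated
structurally (complete over all 10 combinations, unacclimatized ≤
acclimatized per class, strictly decreasing with workload) and
behaviourally — applied to the packaged 47-case table it yields exactly the
published 45/47 exceedance count, with the same two non-exceeding cases.
The table is data: any YAML/JSON file passing the same validation can
replace it, and the sensitivity is visible (raising the acclimatized-high
limit from 25 to 26 °C flips the borderline 25.87 °C case, dropping the
count to 44).

**Workload mapping.** Cases flagged as heavy physical work (intense arm and
trunk work, carrying heavy material, pushing or pulling loaded carts) map
to class *high*; all other cases map to *moderate*, on the grounds that
compensated outdoor manual work is never resting or light. The mapping,
too, reproduces the published exceedance count.

## Case derivation and cohort summary

`derive_flags()` fills a case's exposure flags from weather: tropical night
from the night preceding onset, heat wave from whether the onset day lies
inside a detected episode (not merely near one), and `wbgt_max` as the
maximum valid estimated WBGT over a window of `wbgt_window_days` calendar
days ending at onset. The window defaults to the onset day alone: the
3-day weather retrieval around each case supports the heat-wave and
tropical-night rules, and which window the published per-case WBGT maxima
used was not stated, so the narrowest defensible window is the default and
wider ones are opt-in. Weather must cover the onset day and the 3 prior
days or the derivation refuses with the list of missing days.

`summarize_cohort()` reports counts and percentages rounded **half-up to
one decimal**, matching how the cohort results are printed (base R's
round-half-to-even would print 46.85 → 46.8 either way, but ties like
0.25 → 0.3 differ). Indeterminate flags count as absent and are reported
separately, never silently folded into either side. Ages bin into decades
[20, 30), …, [70, 80).

One discrepancy is documented rather than hidden: the published results
text gives an age-decade distribution of (3, 4, 13, 15, 10, 2), but the
published row-level 47-case table — the only recomputable source, and the
one this package ships — yields (2, 4, 14, 16, 9, 2). No computation on the
row-level data can recover the text's counts; the package treats the
row-level table as authoritative, and the acceptance test that asserts the
text's distribution fails by exactly this difference, on purpose. All five
headline proportions (61.7 %, 78.7 %, 46.8 %, 87.2 %, 95.7 %) reproduce
exactly. Similarly, a handful of table rows carry heat-wave absence flags
alongside WBGT values near 30 °C; the package takes the printed per-case
flags as ground truth rather than re-deriving them, since the station
assignments behind them were never published.

## Synthetic generators

`generate_weather()` emulates the *structure* the analysis assumes in
summer urban station data — a diurnal cycle with minimum near 06:00 and
maximum near 15:00 (two half-cosine arcs: 9 h warming, 15 h cooling),
declared heat-wave episodes that lift afternoons to a chosen peak without
touching nights, declared tropical nights enforced by a 26 °C floor over
the night window, humidity anti-phased with temperature and clipped to
[5, 99] %, and additive Gaussian noise. It does **not** emulate synoptic
weather: no autocorrelated air masses, no rain or fronts, no
station-to-station correlation, no humidity physics. Passing tests
therefore show the pipeline's rules are implemented correctly, not that
the pipeline would be robust to real-world data pathologies (sensor
dropouts excepted — those are exercised directly).

Defaults are chosen as a plausible Korean summer month: 30 days, base mean
25 °C, diurnal half-range 5 °C (ordinary days peak at 30 °C, below the
advisory threshold), humidity 65 ± 20 %, noise 0.5 °C.

`generate_cohort()` draws independent Bernoulli flags, uniform ages and a
truncated-Gaussian WBGT. Its defaults are the published cohort's observed
margins: n = 47, heavy 41/47, unacclimatized 22/47, heat wave 29/47,
tropical night 37/47, WBGT mean 29.9 °C and sd 2.0 °C (the 47 printed
values have mean 29.92 and sd 2.05), ages 29–77 (the printed range).
Independence of the flags is a simplification — in the real cohort heavy
exertion and acclimatization are plainly not independent — which is
acceptable because the generator's job is marginal-structure recovery, not
joint realism.

**Parameter recovery.** At n = 1000 over seeds 1–20, each configured
prevalence is recovered by `summarize_cohort()`; the test accepts a
per-seed count inside the central 99 % binomial band in at least 19 of the
20 seeds (the band itself misses ~1 % of draws, so demanding 20/20 across
80 draws would fail a correct generator roughly half the time) and
additionally requires the seed-pooled count (n = 20 000) inside its own
99 % band. Problem sizes throughout the suite — 1000-point formula-oracle
comparisons, 100 random 60-day event sequences, 20 × 1000 cohort draws —
were chosen so each property is tested at a scale where its failure modes
can actually appear while the whole suite stays interactive.

## Numerical choices and degenerate inputs

* Timestamps are naive local civil time stored as fixed-offset POSIXct;
  the analysis never crosses time zones and station exports carry no
  offset.
* Seeded generation uses `withr::with_seed`, so library calls never
  disturb the caller's RNG stream; the seed is recorded on the output.
* The truncated-Gaussian WBGT draw resamples out-of-band values rather
  than clipping, preserving the distribution's shape within [18, 38] °C.
* Empty series, empty cohorts, unsorted summaries, missing limit-table
  combinations, non-finite meteorological inputs and missing `wbgt_max`
  all raise classed errors (`heatstrain_empty_input`,
  `heatstrain_order_error`, `heatstrain_config_error`, …) rather than
  propagating NA.
* Percent rounding adds a √ε nudge before truncation so decimal ties that
  sit just under .5 in binary still round up.

## Limitations

* The WBGT estimate uses only Ta and RH; solar radiation and wind are
  absent, so the estimate degrades for strongly irradiated or windy sites.
  Alternative estimators (Liljegren, Bernard) are out of scope.
* The limit table is a screening table for continuous work in light
  clothing; clothing-adjustment factors, work/rest cycling and continuous
  metabolic-rate limit curves are not implemented.
* Nearest-station selection is out of scope: the package consumes one
  series per analysis and does not know station coordinates.
* The cohort summaries are descriptive, as in the source case series — no
  inferential statistics are computed.
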