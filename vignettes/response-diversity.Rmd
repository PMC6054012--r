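---
title: "Assessing response diversity and adaptive-capacity gaps in variety trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing response diversity and adaptive-capacity gaps in variety trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respdiv)
```

## The problem

Perennial forage crops — timothy, the fescues, festulolium, red clover —
carry northern European dairy production, and their yields are exposed to
weather in every season: hardening conditions in autumn, frost and thaw
over winter, heat and drought during the cutting season.  A cultivar pool
adapts to a changing climate not only through the mean performance of its
members but through *response diversity*: if cultivars react differently
to a weather factor, growers and breeders can buffer against it; if every
cultivar reacts alike to a factor that clearly matters, the pool has a
*gap in adaptive capacity* with respect to that factor.

`respdiv` implements that assessment as a tested pipeline over two plain
inputs: a daily weather series per trial site and the multi-year records
of official variety trials (annual dry-matter yield per cultivar, site,
year and experiment, with cut dates).  Because official trial records are
generally not redistributable, the package ships a seeded synthetic-data
module that generates both inputs with known ground truth, so every stage
of the pipeline is verifiable end to end.

## Season segmentation

Each harvest-year season at a site is split into three periods:

* **Fall hardening (FH)** starts on the last day, from 1 August of the
  preceding year, on which the running balance of cold degree-days below
  5 °C minus degree-days above 5 °C is still zero, and ends on the last
  day of the first spell with minimum temperature ≤ −10 °C.  The balance
  is floored at zero: summer warmth does not bank a deficit that autumn
  cold must first repay.  We chose the floored over the cumulative
  reading because, under any realistic boreal August, a cumulative
  balance goes several hundred degree-days negative and only recovers in
  mid-winter — after the first killing frost — which would make almost
  every season degenerate and is incompatible with observed FH lengths of
  roughly one to three months.
* **Winter (WP)** runs from the day after FH ends to the day before the
  growth period starts.
* **Growth (GP)** starts on the fifth day of the first run of five
  consecutive days with mean temperature above 5 °C and ends with the
  season's last cut — which is experiment-specific, so the same site-year
  can segment differently across experiments.

Degenerate seasons are flagged, never silently dropped or zero-filled:
`fh_no_frost_capped` (no −10 °C day before 30 April; FH end capped
there), `fh_degenerate` (frost before the balance start, or the balance
never settles — FH reported absent), `no_gp_spell`, and
`incomplete_weather` (a missing day anywhere in a required window fails
that season rather than being interpolated).  A multi-day first frost
spell ends FH on the spell's *last* day; a single frost day is a spell of
length one.

The engine is checked against a literal brute-force oracle — an O(n²)
day-by-day re-derivation of the rules — on hundreds of seeded synthetic
years, with exact span agreement required.

## The 14 agroclimatic variables

`acv_registry()` enumerates the variable set: FH length, cold
accumulation below 5 °C and mean daily rainfall during FH; warm-day
accumulation rate above 0 °C and the count of ≤ −15 °C cold-stress days
during WP; and, over the growth period, the temperature sum above 5 °C
and its daily rate, heat-day counts (tmax ≥ 25 °C split at the first cut,
tmax ≥ 28 °C overall), the post-first-cut temperature sum over 7 days,
and precipitation totals (GP start to cut 1, cut 1 to cut 2, and the 14
days after cut 1).

Conventions worth stating: heat-day thresholds are *at least* 25 °C
(28 °C), since exact equality is a measure-zero event on real data;
cold-stress days use the daily *minimum* (consistent with the FH frost
rule); post-cut windows start the day after the cut; the primary-growth
window includes the cut day itself; and the post-cut and winter warmth
sums accumulate positive daily means (base 0 °C) — a base of 5 °C over
seven mid-summer days could not reach the magnitudes (≈ 100–140
degree-days) these variables are known to take, while ≈ 17 °C daily means
at base 0 do.  A variable whose period is absent or whose unit lacks a
second cut is returned *missing with a reason*, and missingness is
monotone in the flags.

## Tertile categorization

For each variable, environment units (site × year × experiment) are
ranked by value and cut into low/moderate/high categories.  Balance is on
*observations* — so that each category's yield estimate is about equally
reliable — but the integrity constraint operates on units: all
observations of a unit share its label, and exactly tied unit values
share a label.  The partition minimizes the largest deviation of a
category's observation count from N/3, by exhaustive search over break
positions between tie blocks; among optima the lowest breaks win, making
labels deterministic.  Tests compare against an independent
exhaustive-partition oracle.

## The mixed model

Per species and variable, the package fits by REML

$$y = \mu + \mathrm{cultivar}_i + \mathrm{category}_j +
(\mathrm{cultivar} \times \mathrm{category})_{ij} + u_{\mathrm{unit}} +
\varepsilon,$$

with the unit intercept $u$ random (each unit nested in one category) and
everything else fixed.  Marginal (Type-III) F tests with Satterthwaite
denominator degrees of freedom give p-values for G, E and G×E; a
residual-df fallback is available (`df_method = "residual"`) and the
method used is recorded in the results.  We use Satterthwaite rather than
the containment method of older mixed-model software; p-values can differ
slightly in the tails, but the classification thresholds, not any
particular df recipe, are the contract.  Least-squares means per
cultivar × category come from `emmeans`.  Optimizer tolerances are 1e-8
with a generous iteration cap; singular fits (unit variance at zero) are
legitimate and reported, not errors.

All observations, including long-term control cultivars, enter
estimation; response profiles, max-diff and gap flags are reported only
for *reporting cultivars* — those tested in the reporting window
(default 2000–2012) with at least 20 usable observations for the variable
at hand, recounted per variable.

Derived statistics:

* **Response profile**: each reporting cultivar's LS-mean per category as
  a percent of the species' average yield over reporting-cultivar
  observations (100 % = species average).
* **Max diff**: per cultivar, the high-minus-low LS-mean contrast; the
  statistic is the spread (max − min) of those contrasts, signed by the
  species-level high-minus-low contrast.  The sign convention is a
  reconstruction — published tables print signed values without defining
  the sign — and we attach the direction of the species-level response as
  the most informative reading.
* **Gap rule**: a variable is a gap when E is significant and G×E is not,
  both at α = 0.05 by default (configurable).  The star scheme
  (* 0.10, ** 0.05, *** 0.01, **** 0.001) is reported alongside;
  "significant" in the gap rule means the 0.05 level, not the 0.10
  tendency level.

## The synthetic-data module

The weather generator is a sinusoidal annual cycle plus AR(1) anomalies
(default: mean 3 °C, amplitude 14 °C, warmest day 200, AR 0.7, innovation
SD 2.5 °C), min/max offsets of 4 °C with jitter, and Bernoulli-gamma
rainfall (wet-day probability 0.45, shape 0.8, scale 4 mm).  These
defaults emulate a boreal station: winters reliably produce −10 °C
frosts and −15 °C stress days, springs produce the 5-day warm spell, and
in practice essentially every generated year segments cleanly.  The
generator does *not* mimic any particular station's normals, snow cover,
or the spatial correlation of a real network — passing tests show the
pipeline's logic is right, not that any specific climate is reproduced.

The trial generator runs the mixed model forward over a simulated network
(default 5 sites × 3 years × 2 experiments, 6 cultivars): grand mean
7000 kg DM ha⁻¹, cultivar SD 300, category effects (−500, 0, +500),
σ_unit = 1000, σ_ε = 400 — the unit component deliberately dominates, as
it does in real trial networks — and a planted interaction expressed as a
cultivar response range (each cultivar's high-minus-low response, spread
evenly over the range).  Category effects are planted on the *true*
tertile of a chosen agroclimatic variable computed from the generated
weather, so categorization is exercised against known truth.  Cut dates
follow day-of-year rules (cut 1 ≈ 170, cut 2 ≈ 220, optional third cut
≈ 255, jitter SD 4 d), and `mask_cut_dates()` reproduces the ~1 %
missing-harvest-date blemish of real archives.

Calibration studies in the test suite use this design at 30 units and 500
(null) / 200 (power) replicates: the interaction test holds its nominal
5 % level, power reaches 1 at a planted response range of 1500 kg ha⁻¹,
and the mean recovered max-diff sits within a few percent of truth (the
max-of-contrasts statistic carries a small upward noise bias by
construction).

## Numerical and design choices

* "Balance was zero" is tested as ≤ 0; exact floating zeros are not
  required.
* Dates are whole calendar days; all spans are inclusive on both ends.
* Cut-date imputation uses a small mixed model (species and cut-number
  fixed, site-year random intercept on day-of-year), rounds to whole
  days, clamps into the observed site-year harvest range, and *refuses*
  to guess when a site-year has no observed date for the needed cut —
  such observations are excluded from variable computation, mirroring
  standard practice.
* No multiple-testing correction is applied across the 14 variables, by
  design: the assessment inspects each factor on its own terms.
* Species are analysed independently.

## Limitations

The synthetic module validates logic, not climate realism; no snow-cover,
soil-frost or ice-encasement processes are modelled; missing weather days
are flagged and excluded, never interpolated; and the gap rule inherits
the usual caveat of accept-the-null reasoning — a non-significant G×E in
a small cultivar set is weak evidence of true response uniformity.
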