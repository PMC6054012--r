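# respdiv

Response diversity and adaptive-capacity gaps in multi-environment
variety trials.

## What it does

Forage crop production in northern Europe depends on how a species'
cultivar pool responds to weather — autumn hardening conditions, winter
frost, growing-season heat and rain.  A pool adapts well to a changing
climate when its cultivars respond *differently* to a critical weather
factor (response diversity); when a factor clearly affects yield but
every cultivar is hit alike, the pool has a **gap in adaptive capacity**
with respect to that factor.

`respdiv` turns that assessment into a tested pipeline over two plain
CSV inputs (daily weather per site; variety-trial yield records with cut
dates):

1. **Segment** each site-season into fall hardening (FH), winter (WP) and
   growth (GP) periods.  FH starts when a zero-floored balance of cold
   minus warm degree-days around 5 °C last sits at zero after 1 August
   and ends with the first ≤ −10 °C frost spell; GP starts on the fifth
   day of the first 5-day spell above 5 °C and ends with the last cut.
2. **Compute** 14 agroclimatic variables per trial environment
   (site × year × experiment): period lengths, degree-day sums and rates,
   heat- and cold-stress day counts, rainfall aggregates anchored on the
   cut schedule.  See `acv_registry()`.
3. **Categorize** environments into observation-balanced low/moderate/high
   tertiles of each variable (units never split across categories).
4. **Fit**, per species × variable, the REML mixed model

   `yield = mu + cultivar + category + cultivar:category + (1 | unit) + error`

   with Type-III F tests (Satterthwaite df) for G, E and G×E, and
   least-squares means per cultivar × category.
5. **Assess**: response profiles as percent of the species average,
   the signed max-diff statistic (spread of cultivar high-minus-low
   responses), significance stars, and the gap rule —
   **gap ⇔ E significant and G×E not** (α = 0.05, configurable).

A seeded synthetic-data module (`generate_weather()`,
`generate_trials()`) produces boreal weather and trial networks with
known planted truth, so segmentation, categorization and the G×E
analysis are testable end to end without access to official trial
records, which are typically not redistributable.

## Worked example

A demonstration run simulates a 5-site × 3-year × 2-experiment network
(6 cultivars, 180 observations) with a strong planted category effect and
*zero* planted interaction on the GP temperature sum — a gap by
construction — and analyses it:

```r
library(respdiv)
cfg <- demo_pipeline_config(outdir = "demo_out", seed = 1)
res <- run_pipeline(cfg)
res$results[, c("species", "variable_id", "n_obs", "p_E", "p_GxE",
                "stars_E", "stars_GxE", "max_diff", "gap")]
#>   species variable_id n_obs   p_E p_GxE stars_E stars_GxE max_diff  gap
#> 1 timothy    GP_TSUM5   180 0.013  0.97      **                312 TRUE
head(res$profiles[, c("cultivar", "category", "lsmean", "percent_of_average")])
#>   cultivar category lsmean percent_of_average
#> 1     CV01      low   6324              90.80
#> 2     CV02      low   6177              88.69
#> 3     CV03      low   6076              87.23
#> 4     CV04      low   6046              86.80
#> 5     CV05      low   5973              85.76
#> 6     CV06      low   7036             101.03
```

Reading the output: the environment effect is significant
(p_E = 0.013, `**`) — the temperature-sum category genuinely moves
yields — while the interaction is nowhere near significant
(p_GxE = 0.97): all six cultivars respond alike, so the variable is
flagged `gap = TRUE`.  The max-diff of 312 kg DM ha⁻¹ is the residual
spread among cultivar responses (truth: 0).  Profiles express LS-means
as percent of the species' average yield; the low-category cells sit
below 100 % because the planted low-category effect is −900 kg ha⁻¹.
`run_pipeline()` also writes `segmentation.csv`, `variables.csv`,
`categories.csv`, `results.csv`, `profiles.csv` and a `manifest.json`
run record to the output directory.

The package also ships the published per-species summary of the Finnish
official variety-trial analysis it follows (`reported_gxe_table()`), so
the gap logic can be checked against reported results:

```r
tab <- gap_assessment(reported_gxe_table())
tapply(tab$sig_gxe, tab$species, sum)
#>   festulolium meadow_fescue    red_clover   tall_fescue       timothy
#>             8             1             1             2             0
```

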