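# nightcross

Circadian flight timing and water-barrier crossing decisions in a
diurnally migrating songbird.

Purple martins (*Progne subis*) are textbook diurnal, fly-and-forage
migrants, yet GPS tracks of their spring migration show long open-water
crossings of the Caribbean Sea and Gulf of Mexico that cannot fit inside
12 h of daylight. `nightcross` is an analysis pipeline for exactly this
kind of data: fixed-schedule GPS tags (two or three fixes per day at
preset local times), a land/water mask, and gridded reanalysis winds. It
is written for movement ecologists who want to ask *when* birds fly
(day vs night), *where* (land vs water), and *what drives the decision
to launch a water crossing instead of detouring around it*.

## What the package computes

Tracks are cut into nominal 12-h segments between scheduled fixes
(1800–0600 and 1600–0400 local are night; 0600–1800 and 0400–1600 are
day; interior fixes of 3-slot tags become distance-refining waypoints).
Each segment gets a great-circle distance, a speed, minutes of daylight
(NOAA solar equations, zenith 90.833°, evaluated at the segment's
endpoint locations), and a land/water surface label from a polygon mask.

At each coastal **departure point** — the last over-land fix before a
bird either crosses a waterbody or turns away to circumnavigate it — the
pipeline derives two covariates:

* **tailwind assistance** `Ta = u·sin(θ) + v·cos(θ)` (m/s), the wind
  vector interpolated from a 2.5°/6-hourly U/V grid projected onto the
  assumed optimal crossing direction θ;
* **water:land ratio**, the water-crossing distance divided by the
  shortest land-constrained (circumnavigation) distance between the same
  endpoints, computed on a water-avoiding visibility graph. A ratio near
  1 means crossing saves almost nothing.

The decision model is a Bayesian mixed-effects logistic regression,

```
cross_i ~ Bernoulli(p_i)
logit(p_i) = β0 + β1·tailwind_s + β2·ratio_s + β3·night_i + u_bird(i)
u_b ~ Normal(0, σ²)
```

with weakly informative priors (coefficients `Normal(0, 5²)`,
`σ ~ half-t(3, 0, 2.5)`), sampled by an adaptive Metropolis-within-Gibbs
MCMC with split-R̂/ESS diagnostics, plus the Bayes R² summary
`R² = Var(p̂) / (Var(p̂) + mean(p̂(1−p̂)))` per posterior draw. A linear
regression of log flight distance on per-segment daylight minutes probes
whether "night" flights actually ride the twilight.

Because raw tracking data of this kind is rarely deposited, the package
ships a synthetic world generator (`make_world()`, `simulate_tracks()`,
`simulate_departures()`): two water barriers 150–1100 km wide, an
autocorrelated wind grid, and 11 birds on realistic tag schedules whose
coastal decisions follow a known logistic law — so the whole pipeline is
testable end-to-end against ground truth.

## Worked example

Simulate 200 coastal decisions from a known law and recover it:

```r
library(nightcross)

dep <- simulate_departures(n = 200, true_beta = c(2, 1, -2, -1),
                           sigma_bird = 0.5, seed = 7)
fit <- fit_crossing_model(dep, chains = 2, iter = 1200, seed = 1)
fit
#> Bayesian mixed logistic crossing model
#>   200 departures, 20 birds, 2 chains x 1200 iterations (600 warmup)
#>
#> Population-level effects (logit scale, continuous covariates scaled):
#>            Estimate Est.Error l-95% CI u-95% CI Rhat Bulk_ESS Tail_ESS
#> Intercept      2.07      0.41     1.28     2.92 1.05    59.27    77.37
#> Tailwind       0.68      0.24     0.25     1.16 1.01    83.26   160.19
#> Water:Land    -2.09      0.31    -2.69    -1.43 1.03    70.31   110.98
#> DayOrNight    -1.03      0.41    -1.92    -0.29 1.03    87.75    88.05
#>
#> Group-level effect:
#>            Estimate Est.Error l-95% CI u-95% CI Rhat Bulk_ESS Tail_ESS
#> sigma_bird     0.98      0.34     0.47     1.76 1.06    41.92   164.09

round(bayes_r2(fit), 2)
#> mean   sd  l95  u95
#> 0.45 0.06 0.32 0.55
```

The posterior means sit on the generating coefficients `(2, 1, −2, −1)`
and every 95% interval covers its truth: the ratio effect is sharply
negative (birds cross when crossing saves distance), the night effect
moderately negative. `predict(fit, newdata)` returns posterior crossing
probabilities; `plot(fit)` draws the coefficient intervals.

The full file-based pipeline runs from four plain-text inputs:

```r
fs  <- write_fixture_set("fixtures", seed = 42)   # or your own data
cfg <- pipeline_config(fixes = "fixtures/fixes.csv",
                       schedules = "fixtures/schedules.json",
                       mask = "fixtures/mask.geojson",
                       wind = "fixtures/wind.csv",
                       out_dir = "results",
                       optimal_dirs = fs$world$optimal_dirs)
res <- run_pipeline(cfg)
```

and writes `segments.csv`, the per-bird summary tables, `departures.csv`
with covariates, `model_summary.csv`, `bayes_r2.csv`,
`daylight_regression.csv`, windrose/bearing tables, and a JSON manifest;
reruns with the same config and seed are byte-identical. A thin shell
wrapper lives at `inst/scripts/nightcross.R`
(`run` / `simulate` / `validate` subcommands).

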