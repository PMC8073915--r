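---
title: "Methods: segmenting circadian flight timing and modelling barrier-crossing decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting circadian flight timing and modelling barrier-crossing decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightcross)
```

This vignette documents the modelling choices behind `nightcross`: what
each stage assumes, which parameters matter and why their defaults are
what they are, what the synthetic world does and does not emulate, and
the numerical corner cases.

## 1. Track segmentation

GPS tags in this study design record on *fixed local schedules* — 0600
and 1800 Central Daylight Time for most tags, 0400/1600 Eastern Daylight
Time for others, and two three-slot programmes (0000/0600/1800 and
0400/1000/1600). We treat schedule labels as fixed UTC offsets (CDT =
UTC−5, EDT = UTC−4) and ignore daylight-saving transitions: the tags
themselves used fixed daylight-time labels, so a civil-time library
would add complexity without changing any interval.

The unit of analysis is the **12-h segment** between consecutive
scheduled fixes. Segments starting at 1800 (or 1600) local are *night*,
those starting at 0600 (or 0400) are *day*. Interior fixes of three-slot
tags (0000 inside the 1800→0600 night, 1000 inside the 0400→1600 day)
are kept as **waypoints**: they refine the along-path distance of the
containing segment (a dog-leg sum of great-circle legs) but never define
a phase boundary, so every tag contributes at most two comparable
segments per day. Consecutive fixes must be 12 h ± 1 h apart to form a
segment; the ±1 h absorbs acquisition jitter while being far too small
to merge distinct scheduled intervals. Larger gaps simply break the
chain and are logged.

**Trimming to the migratory period.** Residency at the wintering and
breeding grounds must be removed before movement statistics mean
anything. The rule here is a stationarity heuristic: leading and
trailing maximal runs in which every fix stays within
`stationary_radius_km` (default 30 km) of the run's first fix *and* the
run spans at least `stationary_days` (default 3 days) are dropped.
Interior pauses (stopovers) are never touched. 30 km comfortably
contains roosting and foraging excursions of an aerial insectivore
around a colony while being far smaller than a single day's migratory
leg; 3 days separates residency from weather holds. Both thresholds are
exposed in `pipeline_config()` because the right values are a judgement
call about the study system, not a law.

## 2. Geodesy and solar computation

All distances are great-circle (haversine) on a sphere of radius
6371.0088 km. At the 100–1100 km scale of barrier crossings the
difference from ellipsoidal geodesics is below 0.5%, far inside every
tolerance used downstream, and a single convention avoids mixing two
distance tools.

Sunrise and sunset use the NOAA low-precision solar equations at zenith
90.833° (sun's upper limb under standard refraction — the civil
ephemeris convention; no twilight categories). The implementation
iterates the event time twice so declination and the equation of time
are evaluated at the event rather than at noon; unit tests hold it
within ±2 min of an independently computed ephemeris at ten benchmark
locations from the equator to 64° latitude. Polar regimes are flagged
(`polar_day` / `polar_night`) and contribute full or zero daylight; they
cannot occur on this study's routes but the code paths are exercised.

**Daylight per segment** follows the endpoint-based definition: a day
segment's daylight is the overlap of the segment's time span with
[sunrise at the *start* location, sunset at the *end* location]; a
night segment accumulates evening light before sunset at its start
location plus morning light after sunrise at its end location, clipped
to the segment duration. Each sunrise/sunset instance is the one
*nearest the relevant endpoint time*, which resolves the date-boundary
ambiguity for night segments spanning local midnight. An alternative
reading — integrating daylight along the moving bird — differs from the
endpoint definition by at most a few minutes for 12-h segments at
songbird speeds; the test suite quantifies the endpoint definition
against a minute-resolution brute-force integration and holds agreement
to ±2 min on randomized segments.

## 3. Surface classification and movement summaries

The land/water mask is a set of named simple polygons in lon/lat;
everything outside them is land. Point-in-polygon uses even-odd ray
casting in coordinate space, appropriate for regional, non-polar masks.
A segment's great circle is sampled every `step_km` (default 1 km) and
each step attributed to water if its midpoint falls in a polygon; the
segment is a *water flight* when more than `surface_majority` (default
0.5) of its distance is over water. The majority rule assigns whole
segments, matching how flights are tallied in the field literature; the
threshold is configurable because a 0.5 cut on a 12-h segment is a
coarse instrument near coasts.

Per-bird summaries report counts of day/night water flights, per
phase-by-surface distance and speed means with standard errors, maxima,
and the largest distance covered in any window of consecutive segments
spanning ≤ 24 h. **The standard error convention is the population
(divisor-n) standard deviation over √n**, so single-observation cells
print as "x ± 0.00". This differs from the more common n−1 convention
and is chosen deliberately for consistency with the cohort summary
tables this package reproduces; `group_mean_se()` documents it
prominently. Whole-number percentages round half away from zero.
Speed-table aggregation is a per-segment unweighted mean (the per-km
weighting is another defensible choice; unweighted matches the
segment-as-unit design).

## 4. Wind covariates

Winds live on a regular lat/lon grid (2.5° in the source reanalysis) at
6-hourly steps, as eastward U and northward V components. Queries use
trilinear interpolation (bilinear in space, linear in time), which is
exact at nodes and on affine fields — both properties are tested.
Because no NetCDF reader is part of the package's dependency set, the
loader consumes a plain CSV dialect (`time,lat,lon,u,v`, complete
lattice); the writer emits the same, so fixtures round-trip.

Direction uses the oceanographic **"toward"** convention (0° = north,
the direction the air moves to), matching how windroses of flight
support are read; `speed_dir()` also returns the meteorological "from"
direction. Tailwind assistance is the projection
`Ta = u·sin θ + v·cos θ` onto the optimal crossing direction θ, with no
airspeed term — deliberately, since the decision covariate is about
available support, not realized drift compensation. Optimal directions
per waterbody follow the flyway geometry (Caribbean 270°, Gulf of
Honduras 315°, Gulf of Mexico 315/0/45° by Texas/Manitoba/Florida
destination); for synthetic worlds a configuration map overrides these
names.

## 5. Departure points and the distance-savings covariate

Crossing departures are read directly off the segment classification:
each maximal run of water segments is one crossing event, its departure
the last over-land fix before the run. Detours were identified by eye in
the original field workflow; here they are three explicit geometric
conditions on a land fix, all configurable: within `coastal_buffer_km`
(50 km) of a water polygon; the ray along the optimal direction
intersects that polygon for at least `min_block_km` (100 km — the
barrier genuinely blocks the preferred course); and the realized next
bearing deviates from the optimal direction by at least
`detour_angle_deg` (60° — a reorientation, not drift). Consecutive
qualifying fixes at the same waterbody collapse to the first, and a fix
that actually enters water is always a crossing.

The crossing distance runs from the departure fix to the first
subsequent over-land fix whose straight path crosses the waterbody and
after which motion continues within 90° of the optimal direction (for
detours this is the *hypothetical* crossing the bird declined).
Departures with no such far-side fix are excluded with a logged reason —
the same bookkeeping as the one excluded decision point in the source
cohort. The circumnavigation alternative is the shortest water-avoiding
polyline between the same endpoints, computed on a visibility graph
over the endpoints and polygon vertices (vertices nudged ~10 m outward
so boundary-hugging edges are walkable), with geodesic edge weights and
Dijkstra search. Tests hold it within 1% of an independent fine-lattice
search with rubber-band smoothing. The ratio of the two distances is the
distance-savings covariate; both continuous covariates enter the model
scaled and centred (divisor n−1), with raw values retained for
reporting.

## 6. The crossing model

The decision model is Bernoulli with logit link:

$$\mathrm{logit}\,P(\text{cross}_i) = \beta_0 + \beta_1\,\text{tailwind}_{s(i)} + \beta_2\,\text{ratio}_{s(i)} + \beta_3\,\text{night}_i + u_{b(i)},\qquad u_b \sim \mathcal N(0,\sigma^2)$$

with the random intercept absorbing repeated decisions by the same
bird. **Priors are weakly informative rather than flat**: coefficients
`Normal(0, 5²)` and `σ ~ half-Student-t(3, 0, 2.5)`. With a few dozen
decisions and covariates that can separate the outcomes, improper flat
priors make the posterior fragile or improper; a ±10 logit-unit prior
range is far wider than any plausible behavioural effect yet keeps every
fit proper. This is a deliberate, documented divergence from
"default uninformative priors"; sensitivity can be probed by raising
`beta_prior_sd`.

Inference is an adaptive Metropolis-within-Gibbs sampler: the four fixed
effects update as one block with a proposal covariance adapted from the
warmup history (target acceptance ~0.3), each random intercept and
log σ update as scalar random walks tuned to ~0.44 acceptance, and all
adaptation stops at the end of warmup (first half of `iter`). Defaults
are 4 chains × 2000 iterations. Convergence is summarised by split-R̂
and by bulk/tail effective sample sizes (autocorrelation-based, via
`coda`); the contract is on converged posterior summaries, not on the
sampler brand. Initial values come from a penalised-free `glm.fit`
clipped to ±5, or zero if that fails. Complete separation is detected
and flagged with a message — the fit proceeds, regularised by the
priors. Degenerate designs (all-identical outcomes, a single bird) are
errors.

Bayes R² is computed per posterior draw *s* as
$R^2_s = \operatorname{Var}_i(\pi_i^{(s)}) / (\operatorname{Var}_i(\pi_i^{(s)}) + \operatorname{mean}_i \pi_i^{(s)}(1-\pi_i^{(s)}))$,
the fitted-probability variance over itself plus the expected Bernoulli
residual variance — bounded in [0, 1] by construction.

The daylight regression is ordinary least squares of
`log(distance_km + 1)` on per-segment daylight minutes, per phase. The
+1 km offset accommodates genuine zero-distance segments, which the log
alone cannot.

## 7. The synthetic world

`make_world()` builds a self-contained study system in real lon/lat
coordinates centred near 15°N, 75°W, so the geodesic, solar and wind
code runs unmodified: two rectangular-to-trapezoidal water barriers (a
"sea" narrowing from ~1100 km in the east to ~150 km in the west, and a
~500–900 km "gulf" further north), a 2.5°/6-hourly wind grid with a
configurable mean vector plus AR(1) noise (default mean (−2, −1) m/s,
marginal SD 2 m/s, lag-1 correlation 0.75), and reference covariate
moments. `simulate_tracks()` then flies 11 birds (the cohort size this
design emulates) north on the field tag-schedule mix — mostly 0600/1800
CDT two-slot tags, two 0400/1600 EDT, one of each three-slot programme —
at over-land speeds of ~20 km/h by day and ~4 km/h at night, with
per-crossing water speeds of 25–70 km/h continuing through the night.
At each genuine coastal blockage (ray width ≥ 100 km along the optimal
direction) the bird rests 0–2 intervals and then draws its decision from
the logistic law with known coefficients; detouring birds turn 90° and
coast around the barrier. Every decision is recorded with its true
covariates.

Two standardisation regimes coexist by design. The *track* simulator
must decide sequentially, before the season's covariate sample exists,
so it standardises against the world's reference moments (wind
parameters; ratio moments sampled along both coasts at world build
time). The *decision-level* simulator `simulate_departures()`, used for
parameter-recovery experiments, standardises against the realised
sample exactly as `fit_crossing_model()` will — so recovered
coefficients are on the same scale as the generating ones with no
moment mismatch.

What the generator does **not** emulate: GPS position error, missed
fixes, fix-schedule drift, foraging excursions, wind-drift trajectories,
coastline complexity, or ratio distributions concentrated near 1 (its
convex barriers make circumnavigation substantially longer than
crossing, so realised ratios fall mostly below ~0.6). Passing
recovery tests therefore demonstrate that the pipeline's geometry,
covariate construction and inference are faithful to their definitions —
not that those definitions are robust to messy real tracking data.

## 8. Problem sizes and numerical tolerances used in the tests

Parameter-recovery experiments use 100 replicates of n = 200 departures
over 20 birds at 2 chains × 1200 iterations — sizes at which posterior
intervals are stable enough for coverage assessment while a full
experiment runs in minutes on one CPU; the analysis-scale defaults
remain 4 × 2000. The daylight-slope experiment uses 100 replicates of
n = 200 night segments with noise SD 0.4 around a true slope of 0.013
log-km/min, daylight drawn near the observed 4–176 min range.
End-to-end checks run the default 11-bird world; departure recall
against generator truth is required to reach 0.95, and pipeline reruns
under a fixed seed must be byte-identical. Geometry tolerances: solar
events ±2 min; daylight overlap ±2 min against a minute grid;
circumnavigation within 1% of the lattice oracle; trilinear
interpolation exact to rounding on affine fields.

## 9. Known limitations

* The detour definition is geometric; subtle detours (shallow
  reorientations, early inland turns) fall below its thresholds by
  design rather than judgement.
* Daylight is evaluated at segment endpoints, not along the path; at
  higher latitudes or longer segments than this design the difference
  would need revisiting.
* The visibility-graph circumnavigation treats polygon edges as
  straight in lon/lat; for ocean-basin-scale masks at high latitude a
  great-circle-aware graph would be needed.
* The sampler is tuned for the tens-to-hundreds-of-decisions regime.
  For thousands of decisions per bird a gradient-based sampler would be
  more efficient; the posterior summaries, not the algorithm, are the
  contract.
* Fixed UTC offsets deliberately ignore daylight-saving and true local
  solar time; schedules are compared on the tags' own clock.
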