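---
title: "Methods: from radar echoes to migration traffic, airspeeds and weather selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from radar echoes to migration traffic, airspeeds and weather selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nightmtr)
```

This vignette documents the models and procedures implemented in
`nightmtr`, the assumptions behind them, the parameters that matter, and
the numerical and design choices made where the methodology left room.

## Scope and data model

The package operates on three inputs: an echo table (one row per
radar-detected target: timestamp, altitude AGL, ground speed, track
bearing, pulse mode, bird/non-bird class), a long-format table of
atmospheric profiles on pressure levels (temperature, u/v wind, relative
humidity, vertical velocity, cloud cover, geopotential height per
site-hour), and a rain-event log. Upstream echo classification (wing-beat
signature based) is trusted as given; the package never re-classifies.

All bearings are degrees clockwise from geographic north in the *toward*
sense, all timestamps UTC, and the only bearing/component conversions are
`bearing_to_uv()` / `uv_to_bearing()`. Wind direction deserves a note: the
textbook tailwind formula TW = s·cos(α_wind − α_mig) yields a *negative*
value for a perfect tailwind if α_wind is the meteorological "from"
bearing. `nightmtr` therefore stores α_wind = atan2(u, v) as the bearing
the wind blows **toward**, so TW > 0 always means wind support;
`tailwind_component(..., convention = "from")` exposes the opposite
reading for auditing.

## Night segmentation and filtering

A biological night runs from sunset to the next sunrise, computed with the
NOAA solar-position equations at solar elevation −0.833° (the
refraction-corrected disk edge — geometric sunset, not civil twilight; the
choice is flagged because some workflows use −6°). The implementation is
validated against an independently coded NOAA spreadsheet-algorithm oracle
to within 2 minutes. Latitudes beyond 66° are rejected rather than
approximated: the target systems are mid-latitude corridors.

Filters, in order: night window (closed `[sunset, sunrise]`), rain
(half-open `[start, end)` intervals, overlaps merged), bird class, then
altitude/pulse-mode windows — short-pulse echoes kept at `[50, 800)` m AGL
(small birds are undetectable below 50 m and beyond 800 m under short
pulse), long-pulse echoes at `[800, 1500]` m. The interval conventions are
arbitrary but fixed and tested: the two retained bands partition
`[50, 1500]` m with no overlap at 800. Filtering is idempotent, never
mutates a field, and reports per-filter removal counts.

## Migration traffic rate

MTR is defined as birds crossing a 1 km transect perpendicular to the
movement direction per hour; each detected echo is one crossing, so the
per-bin rate is `n / (width_km × hours)`. Nights are cut into clock hours
anchored at sunset (the final partial hour keeps its true duration; an
anchor had to be fixed and sunset is the biologically meaningful one). Per
hour, bin rates are summed over 50 m bins from 50 to 1500 m (bin width is
configurable; only the 1500 m cap is fixed by instrument range); the
nightly MTR is the mean over hours, excluding hours fully covered by rain.
Hour-averaging (rather than averaging radar scan profiles) was chosen and
is flagged as a convention.

Local, non-directional movement (roosting flights, foraging) contaminates
nightly totals. The correction uses the Rayleigh test on the night's track
bearings: with mean resultant length R̄ and n tracks, Z = nR̄² and the
standard approximation
p = exp(√(1 + 4n + 4(n² − R²)) − (1 + 2n)), R = nR̄.
The *directional proportion* is R̄ gated by p < 0.05, and directional
MTR = proportion × nightly MTR. R̄ is the natural estimator here because a
mixture of a tight common heading (weight f) and uniform noise has R̄ → f;
the gate keeps pure-noise nights from passing through. The test suite
checks the type-I rate of the gate against its nominal 0.05 and the
f-recovery at f ∈ {0.3, 0.7, 1.0}.

## Atmospheric covariates at flight altitude

Profiles are interpolated linearly in geopotential height to 500 m above
each radar's elevation — a fixed reference flight level. Below the lowest
level the lowest value is used (clamped and flagged); interpolation is
exact on affine profiles and is checked against densely sampled smooth
profiles. Hourly values inside the night window are averaged per night.

Two conventions matter:

- the nightly wind speed `s` is the **mean of hourly speeds**
  √(u² + v²), not the speed of the mean vector — the latter understates
  wind when direction varies overnight; the choice is flagged;
- the meridional component `v` is sign-flipped in autumn so that positive
  always means wind blowing in the migration direction (north in spring,
  south in autumn); the raw northward `v_raw` is kept alongside, and all
  trigonometry (migration directions, TW) uses the unrotated geographic
  frame.

Night-over-night deltas (temperature, u, v) are missing — not zero — on a
season's first night. Ordinal date is day-of-year with Jan 1 = 1. A
Pearson correlation screen over the numeric predictors flags |r| ≥ 0.7 but
drops nothing: the screen is documentation, the models keep all 15
covariates.

## Flight decomposition

Nightly mean groundspeed is the arithmetic mean of the night's track
ground speeds, computed only for nights with ≥ 5 tracks. The seasonal mean
migration bearing per site is the circular mean of all that site-season's
filtered track bearings, held fixed across its nights. TW projects the
night's 500 m wind (the only level the covariate table defines) onto that
bearing; airspeed = groundspeed − TW.

This is a *scalar* decomposition, reproduced deliberately: it subtracts a
wind projection from a speed rather than doing per-bird vector algebra.
Its bias is well characterised and asserted in tests: exact under pure
tail/headwind with no heading spread; under crosswind variance σ²_cw it
inflates airspeed by ≈ σ²_cw / (2·groundspeed); and under a *persistent*
crosswind that deflects mean track bearings by Δ from mean headings it
deflates airspeed by ≈ (1 − cos Δ)·airspeed. The airspeed-recovery test
therefore runs under mixed (variable-direction, weak-mean) winds, where
the net bias is a few tenths of m/s; under the persistent north-westerly
regime the generator uses by default, the deflation term dominates and the
scalar estimate sits visibly below truth — a property of the method, not a
bug, and the reason the package also retains hidden per-echo ground truth
for auditing.

## Boosted weather-selectivity models

The response is log(directional MTR + 1) — the +1 keeps zero nights
finite, the log meets the Gaussian error assumption. Spring and autumn are
fitted separately (different bird composition, phenology and weather);
the pipeline asserts no row is shared between the two fits.

The boosting core is a thin adapter over xgboost constrained to the
classic stochastic-gradient-boosting setting: trees limited to
`interaction_depth + 1 = 11` leaves (loss-guided growth), shrinkage
0.001, row subsampling 0.5 per tree, squared-error loss, no
regularisation, minimum 10 observations per leaf, single-thread and
seeded, so fits are deterministic seed for seed. The three quantities the
analysis reports are implemented in-package, not taken from library
defaults:

- **Stagewise CV tree selection.** Trees are evaluated in steps of 25.
  Each of 10 folds is trained once and its held-out squared-error deviance
  trace is read per step; the scan walks forward and stops after 3
  consecutive steps without a new minimum of the fold-mean deviance (a
  plateau rule; the classical stopping heuristic leaves the tolerance
  unspecified), selecting the minimising step. The final model is refit on
  all rows at the selected size. A hard cap (`max_trees`, default 5000)
  bounds the scan; if the deviance is still improving there, the cap is
  selected with a warning — at a 0.001 learning rate on a few hundred
  rows this regularly happens, and raising the cap trades minutes for a
  marginally lower CV deviance.
- **Relative importance.** Squared-error split gains are summed per
  variable over all trees of the selected ensemble and scaled to sum
  to 100. Never-used variables score 0; an all-constant response yields an
  all-zero table with a warning.
- **Marginal responses.** Partial dependence: the training rows are
  re-predicted with one covariate pinned to each grid value and averaged,
  on the log scale (optional back-transform exp(·) − 1). Grid points
  outside the observed range are computed but flagged as extrapolation.

`radar_type` is ordinally encoded (two levels, split semantics identical
to one-hot for binary factors). Rows with missing deltas are kept: xgboost
routes missing values along a learned default branch per split. That
differs from surrogate-free exclusion of those rows from splits on those
variables (the simplest classical treatment); with deltas missing only on
each season's first night per site the practical difference is a handful
of rows.

One aliasing caveat surfaced by the synthetic experiments: with very few
sites, radar type is perfectly separable by some geographic covariate, and
greedy trees credit the continuous alias, leaving `radar_type` with zero
importance. Designs need radar types interleaved in latitude, longitude
and elevation (true of any realistically sized network) for the corrective
variable to absorb the detection-efficiency gap.

## Seasonal inference

Speed contrasts use `lmerTest`: `speed ~ season + (1 | site)`, REML, with
Satterthwaite denominator df; a single site downgrades to a Welch t-test
with a warning. In the balanced zero-site-variance limit the season
estimate provably equals the raw mean difference, and the suite asserts
it. Weather comparisons are Welch (unequal-variance) t-tests — pooling was
unspecified and Welch is the safer default — on temperature, u, raw v and
s, judged at the Bonferroni level α/4 = 0.0125. The raw (unrotated) v is
compared, flagged as a choice.

The derived percentage contrasts are asymmetric by construction: the
airspeed percentage references the autumn mean, the groundspeed
percentage the spring mean — reverse-engineered from how such contrasts
are conventionally printed ("X% lower in autumn than spring" for a
spring-referenced difference of speeds computed against the autumn base),
and frozen: differences round to one decimal, percentages to integers.

## The synthetic radar world

The generator emulates the statistical structure the analysis assumes, at
desk scale, with complete hidden ground truth:

- **Weather.** Ten pressure levels (1000–550 hPa) with
  standard-atmosphere heights; sea-level temperature follows a linear
  seasonal trend (spring 12→21 °C, autumn 28→18 °C) plus a nightly AR(1)
  anomaly (sd 4 °C, ρ 0.6) and a 6.5 K/km lapse; wind is an hourly AR(1)
  vector process (component sd 2 m/s, ρ 0.9) around a seasonal mean
  blowing from the north-west (spring 5 m/s, autumn 4 m/s — spring
  windier), increasing ~30%/km with height. Humidity, vertical velocity
  and cloud cover are bounded AR(1) processes.
- **Intensity.** Expected migrants per night =
  base × bell(date; peak, width) × temp-multiplier × wind-multiplier.
  Defaults: base 300 birds/night, peaks mid-April (doy 105, width 15 d)
  and start-of-September (doy 244, width 20 d); temperature multiplier
  min(exp(0.2·(T − 15)), 6) — 1 at 15 °C, monotone, saturating;
  wind multiplier exp(gain·TW) for support, exp(penalty·TW) for
  opposition, exp(−c·|CW|) for crosswind, and exactly 0 at overall wind
  speed ≥ 10 m/s (the hard cutoff), with autumn coefficients
  (0.10/0.15/0.06) stronger than spring (0.05/0.05/0.02): autumn birds
  are the choosier ones. The temperature effect is calibrated so that
  temperature — not the wind terms — is the dominant weather covariate in
  both seasonal fits, which requires cutoff nights to be rare (a few
  percent) and night-to-night temperature variation to be substantial;
  the phenology and selectivity magnitudes are otherwise free parameters
  documented here, since only their shapes are constrained by the
  motivating system.
- **Echoes.** Migrant counts are Poisson(intensity × detection
  efficiency; 1.0 for vertical-looking, 0.1 for weather radars).
  Headings are wrapped-normal (sd 10°) around 0° in spring / 180° in
  autumn; airspeeds normal (16.06 / 13.6 m/s by season, sd 3) truncated
  at 0; each echo's ground velocity is air velocity plus the wind at the
  echo's own hour and altitude — while the analysis uses the fixed 500 m
  level, a deliberate realism mismatch. Bird-classified contaminants
  (10%) fly uniform directions; non-bird clutter (~20/night) exercises
  the class filter; altitudes come from a two-component truncated-normal
  mixture over 0–1500 m; rain events (p = 0.1/night) are logged but
  echoes are retained for the rain filter to remove. Truth (migrant flag,
  heading, airspeed, per-echo wind) goes to a sidecar table no pipeline
  stage reads.
- **Determinism.** Every stream is seeded by hashing the master seed with
  the site/night/purpose, so identical configuration and seed give
  byte-identical output, and partial regeneration is stable.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: radar beam geometry and range-dependent
detectability, insect contamination that defeats the classifier,
topographically steered winds, drift compensation and altitude selection
behaviour, between-year phenology shifts, and spatial correlation of
weather between sites (each site draws independent weather).

## Problem sizes and runtime

The shipped tests run the full seasons of one to six synthetic sites
(90–790 site-nights per scenario), 1000-replicate Rayleigh calibrations,
and boosted fits at the frozen hyperparameters with a 5000-tree scan cap —
sizes chosen so the whole suite completes in minutes on one CPU while
keeping every recovery well out of small-sample noise. The acceptance
script re-runs the same scenarios from a single command-line seed.

## Known limitations

- The scalar airspeed decomposition carries the biases quantified above;
  vector (per-bird) airspeed estimation is deliberately out of scope.
- The Rayleigh p-value approximation is slightly anti-conservative at
  small n; the gate is applied per night where n is typically tens to
  hundreds.
- gbm-style "minimum 25 trees per step" is honoured as the scan
  granularity; selection below 25 trees is impossible by construction.
- With a learning rate of 0.001 the CV deviance often has not plateaued at
  the 5000-tree cap; selected sizes then sit at the cap (warned). The cap
  is configurable.
- Weather radars are represented only through a detection-efficiency
  factor; reflectivity processing of raw volumes is upstream and out of
  scope.
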