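# nightmtr

Analysis of nocturnal bird migration recorded by radar: from echo-level
observations to nightly migration traffic rates, wind-decomposed flight
speeds, boosted-tree weather-selectivity models and seasonal contrasts.

## Who this is for

Radar aeroecologists working with vertical-looking bird radars (e.g.
BirdScan MR1) and/or weather radars processed to bird densities, who need a
reproducible path from filtered echoes and gridded atmospheric data to the
standard quantities of the field:

- **MTR (migration traffic rate)**, birds km⁻¹ h⁻¹: the number of birds
  crossing a theoretical 1 km transect perpendicular to the movement
  direction per hour. Computed per altitude bin and hour, summed over bins,
  averaged per night, and corrected to its *directional* part with a
  Rayleigh test on track directions (proportion = mean resultant length
  R̄ when the uniformity test rejects at α = 0.05, else 0).
- **Tailwind and airspeed**: with the wind vector (u, v) at flight altitude,
  wind speed s = √(u² + v²) and toward-bearing α_wind = atan2(u, v), the
  tailwind component along the seasonal mean migration bearing α_mig is
  TW = s · cos(α_wind − α_mig), and airspeed = groundspeed − TW.
- **Weather selectivity**: boosted regression trees of log(MTR + 1) on 15
  covariates (night-mean temperature, u, v, relative humidity, vertical
  velocity, cloud cover, wind speed at 500 m above the radar, their
  night-over-night deltas, latitude, longitude, elevation, ordinal date and
  radar type), with Gaussian loss, 10-fold cross-validated stagewise tree
  selection (tree complexity 10, learning rate 0.001, bag fraction 0.5,
  steps of 25 trees), split-gain relative importance normalised to 100, and
  partial-dependence marginal response curves.
- **Seasonal contrasts**: linear mixed models of speed with radar site as a
  random intercept (Satterthwaite df), Welch t-tests of weather variables at
  a Bonferroni-adjusted level, and derived percentage contrasts of seasonal
  mean speeds.

Everything is driven end-to-end by a **synthetic radar-world generator**
(sites, seasonal phenology, temperature and wind selectivity, two radar
types with different detection efficiency, rain logs, echo-level ground
truth in a sidecar table), so every stage is testable without any radar or
reanalysis download.

## Worked example

```r
library(nightmtr)

cfg <- demo_config(seed = 3)            # 2 sites, spring + autumn, 30 nights each
run_pipeline(cfg, out_dir = "demo_out") # simulate ... contrasts

fl <- read.csv("demo_out/night_flight.csv")
aggregate(cbind(groundspeed, airspeed, tw) ~ season, fl, mean)
#>   season groundspeed airspeed        tw
#> 1 autumn    17.52571 13.41084  4.114872
#> 2 spring    13.24579 15.57501 -2.329220
```

Autumn birds ride tailwinds (mean TW ≈ +4.1 m/s) and cruise at a lower
airspeed (≈ 13.4 m/s); spring birds fight headwinds (TW ≈ −2.3 m/s) and
compensate with a higher airspeed (≈ 15.6 m/s), close to the generator's
configured seasonal airspeeds (16.06 / 13.6 m/s). The model summary JSONs in
`demo_out/` report the cross-validated tree count, CV correlation and the
importance table; `marginal_responses_*.csv` holds the partial-dependence
curves.

A shell entry point wrapping the same stages lives at
`inst/cli/nightmtr.R`:

```sh
Rscript inst/cli/nightmtr.R demo-config --config cfg.yaml
Rscript inst/cli/nightmtr.R all --config cfg.yaml --out outdir --seed 3
```

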