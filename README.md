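# estuarytrack

Passive acoustic telemetry is the standard way to ask how large mobile
fishes use an estuary: animals carry surgically implanted ultrasonic
transmitters that ping every 30–90 s, and a curtain of moored receivers
logs each ping heard within range (the *effective detection range* is the
distance at which a single transmission is detected with 50% probability,
about 250 m for the arrays this package targets). `estuarytrack` turns
those detection logs into the analyses a movement ecologist reports for a
multi-year estuarine shark study:

- **Presence and residency** — an animal is *present* on a calendar day
  only if ≥ 2 detections were logged that day (discarding spurious single
  detections); the *residency index* is days detected / days monitored;
  arrival, departure and inter-annual return are accounted on a
  September-anchored "shark-year" so one austral summer–autumn occupancy
  season falls in one year.
- **Diel, tidal and depth behaviour** — hourly detection proportions
  standardised by sentinel-tag *standardised detection frequencies* (SDFs)
  to remove diel detection-efficiency bias; hourly *centre-of-activity*
  (COA) distances to the estuary entrance (detection-weighted mean of
  receiver positions along the thalweg); water-column position
  (sensor depth / charted maximum depth: 0 = surface, 1 = seafloor).
- **Spatial hotspots** — receiver-level detections-per-day-deployed rates
  classified by the Getis-Ord Gi* local statistic,

  z_i = [Σ_j w_ij x_j − x̄ Σ_j w_ij] / ( S √{ (n Σ_j w_ij² − (Σ_j w_ij)²)/(n−1) } ),

  with inverse-distance weights on along-channel distance; z > 1.96 is a
  hotspot, z < −1.96 a coldspot.
- **A penalized-spline GAM engine** — binomial, gamma and beta families;
  cyclic cubic smooths for hour-of-day and month; link-scale offsets;
  random intercepts as ridge-penalized group indicators; smoothing
  parameters by GCV on a log grid; AICc model selection with a
  significance tie-break. Used for the monthly-presence, diel, hotspot-
  habitat and environmental models.
- **Environmental hurdle models** — daily presence (binomial) and
  abundance on positive days (gamma) against water temperature, moon
  illumination and rainfall, with the additive effort offset
  log(receivers deployed) + log(sharks tagged).
- **A seeded harbour simulator** — a ~30 km 1-D estuary with a logistic
  detection-range curve calibrated to 50% at 250 m, temperature-driven
  daily occupancy (logit-linear in temperature, p = 0.5 at 22 °C),
  mean-reverting along-channel movement, a diel depth sinusoid, sentinel
  tags, tides and weather — so every stage of the pipeline runs and is
  validated with no external data.

A packaged fixture (`bullshark_records()`) carries the per-shark summary
table of a seven-year, 40-shark bull shark (*Carcharhinus leucas*)
monitoring study in Sydney Harbour, used to reproduce its printed summary
statistics exactly.

## Worked example

```r
library(estuarytrack)

# 1. the packaged study table
rec <- bullshark_records()
ri  <- residency_index(rec$days_detected, rec$days_monitored)
round(range(ri), 2)            # 0.00 0.19  (study-wide residency range)
round(mean(ri[rec$sex == "Male"]), 2)   # 0.05
100 * mean(rec$years_returned >= 1)     # 70  (% of sharks that returned)

# 2. a fully simulated season, analysed end to end
cfg <- sim_config(seed = 42, n_sharks = 4, n_days = 60,
                  study_start = "2013-01-01")
sim <- simulate_harbour(cfg)
cal <- study_calendar(cfg$study_start, cfg$study_start + cfg$n_days - 1)
residency_summary(sim$detections, sim$sharks, sim$receivers, cal)
#>   shark_id days_detected days_monitored residency_index
#> 1 S01                 51             59           0.864
#> 2 S02                 54             59           0.915
#> 3 S03                 45             59           0.763
#> 4 S04                 53             59           0.898

hotspot_analysis(sim$detections, sim$receivers, cal, per_year = FALSE)
#>   receiver_id  rate     z category   (top rows by z)
#> 1 R04         153.   1.94 neutral
#> 2 R05         109.   1.74 neutral
#> 3 R03          96.4  1.54 neutral
```

The simulated sharks are near-resident in mid-summer (high occupancy at
warm temperatures), and without planted aggregation sites no receiver
crosses the ±1.96 hotspot threshold — both exactly what the generating
model says should happen. Planting attraction centres
(`sim_config(hotspot_centres_km = ...)`) produces receivers that Gi*
flags as hotspots, and `run_hotspot_model()` then recovers their
shallow/steep habitat signature.

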