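# fjordtrack

Habitat use and movement analysis for Argos satellite telemetry of
extremely coastal marine mammals — built around the study system of white
whales (*Delphinapterus leucas*) resident among the tidal glaciers and
fjords of a high-Arctic archipelago, tracked in two periods separated by a
collapse of the regional sea-ice regime.

Raw Argos uplinks (one row per fix: animal, UTC timestamp, lon/lat,
location class in {3, 2, 1, A, B, Z}) are turned into hourly,
habitat-classified locations and seasonal models in five stages:

1. **SDA filter** — drops class Z and every fix that needs speed > 3 m/s
   from both kept neighbours or forms an out-and-back *spike* (apex angle
   < 15° with legs > 2.5 km, or < 25° with legs > 5 km). Implemented as an
   exact maximal-retention subsequence search.
2. **On-land particle correction** — each on-land fix spawns 50 particles
   uniform in the disc of its class error radius; the fix moves to the mean
   of the at-sea particles or is removed. (For a fix on a straight coast
   the expected correction is 4R/3π seaward — a closed form the tests use.)
3. **Hourly interpolation** — linear along the track-line onto whole UTC
   hours; gaps > 12 h are left empty; interpolated points on land drop.
4. **Habitat + ice classification** — strict precedence
   Glacier-Fronts (< 5 km from a front) → Fjords (inside a fjord polygon) →
   Coastal (< 5 km from shore) → At-Sea, against epoch-specific geometry;
   six sea-ice types joined from dated polygon fields (nearest day,
   outside coverage ⇒ Open Water).
5. **Models** — per-habitat binomial GAMMs of occupancy vs day-of-season
   (smooth per period, individual random intercept, AR1 within individual)
   and Gaussian mixed models of log speed and turning angle on
   habitat × period with the same error structure.

Because the motivating telemetry is not public, a first-class synthetic
module generates everything with known ground truth: a two-epoch
archipelago (glacier fronts retreat between epochs), four-state
correlated-random-walk whale tracks, Argos-like observations whose
class-dependent errors put ~20–25% of fixes on land, and seasonal ice
fields. Every pipeline stage is tested against that truth.

## Worked example

```r
library(fjordtrack)

sim <- simulate_fixture(fixture_period2(n_animals = 3, mean_days = 25),
                        seed = 8)
cfg <- pipeline_config(sim$argos, sim$model, ice = sim$ice,
                       period = "2013-2016", seed = 8)
out <- run_pipeline(cfg, quiet = TRUE)
out$report[out$report$animal_id == "(all)",
           c("n_raw", "n_onland", "pct_onland", "pct_corrected", "n_hourly")]
#>   n_raw n_onland pct_onland pct_corrected n_hourly
#> 4  2822      566         20            96     5510
out$budgets$pooled[, c("class", "proportion")]
#>            class proportion
#> 1 Glacier-Fronts 0.36152450
#> 2         Fjords 0.41705989
#> 3        Coastal 0.14174229
#> 4         At-Sea 0.07967332
```

Reading: of 2,822 raw fixes, 20% plotted on land (the regime real coastal
whale telemetry shows); 96% of those were rescued by the particle
corrector; interpolation yields 5,510 hourly locations, of which ~36% fall
within 5 km of a tidal glacier front. `summarize_metrics_by_class()` then
gives speed/turn means with bootstrap CIs, `fit_occupancy()` the seasonal
occupancy curves, and `fit_movement_model()` the habitat × period
coefficient table.

The same chain is scriptable:

```sh
inst/cli/fjordtrack simulate --fixture period2 --seed 7 --out simdir/
inst/cli/fjordtrack run --tracks simdir/argos.csv \
    --land simdir/period2_land.geojson --ice simdir \
    --seed 7 --period 2013-2016 --out classified.csv
```

## Documentation

`vignettes/fjordtrack-methods.Rmd` describes the processing model and its
assumptions, every tunable threshold with its default and rationale, what
the synthetic world does and does not emulate, and the numerical design
choices.
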