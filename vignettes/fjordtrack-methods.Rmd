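---
title: "Methods: from raw Argos fixes to seasonal habitat models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw Argos fixes to seasonal habitat models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fjordtrack turns raw Argos satellite uplinks from extremely coastal marine
mammals — the motivating system is white whales (*Delphinapterus leucas*)
resident in a glaciated Arctic archipelago — into hourly, habitat-classified
locations and seasonal occupancy and movement models. This vignette is the
package's own account of the methods: the processing model and its
assumptions, the parameters that matter, what the synthetic world does and
does not emulate, and the numerical choices that were genuinely open.

## 1. The processing chain

### 1.1 Speed–distance–angle (SDA) filtering

Argos positions carry a location class (LC) in {3, 2, 1, A, B, Z} with
class-dependent error; class Z is unusable and is always dropped. The
remaining fixes are screened with a speed–distance–angle filter in the
Freitas tradition: a fix is implausible when

* reaching it from **both** neighbouring kept fixes requires sustained
  speed above `vmax` (default 3 m/s, the species' sustained-swim ceiling), or
* it is the apex of an out-and-back *spike*: the angle between the two legs
  is below 15° with both legs longer than 2.5 km, or below 25° with both
  legs longer than 5 km.

Because the speed rule binds only fixes with two kept neighbours, endpoint
fixes are never speed-removable. Rather than iterating heuristic passes, the
filter solves the declarative problem directly: it returns the
**largest** subsequence of fixes in which no kept triple violates either
rule, breaking ties by keeping earlier fixes (equivalently: removing later
fixes first). This is computed by dynamic programming over the last two
kept fixes with a bounded interior-skip window (default 10 consecutive
removals — far beyond anything observed in real tracks). The result is a
fixed point: filtering a filtered track removes nothing. The test-suite
checks the output against an exhaustive subset search on short tracks.

Distances and angles here (and in interpolation) are Euclidean in a local
azimuthal-equidistant projection centred on each animal's track bounding
box. At archipelago scale (a few hundred km) this is accurate to well under
0.1%, which is orders of magnitude below Argos error; direct geodesic
computation (Vincenty on WGS84) is used for the reported movement metrics.

### 1.2 On-land correction by a simplified particle filter

The study species is strictly marine, yet with coastal animals and
kilometre-scale Argos errors a large share of fixes plot on land. Each
on-land fix spawns `n_particles` (default 50) points uniform in the disc of
its LC error radius; the fix is replaced by the arithmetic mean (in the
local projection) of the particles that fall at sea. Fixes with no at-sea
particle, or whose corrected position is still on land, are removed.
Uniform placement follows the "within a radius" reading; a Gaussian kernel
would concentrate particles near the fix and shift corrections shoreward.
The construction has a sharp analytic consequence used as a test oracle: for
a fix on a long straight coastline the at-sea particles form a half-disc, so
the expected correction is 4R/(3π) ≈ 0.424 R directly seaward.

Points exactly on a boundary count as at-sea (and, for fjord membership, as
inside): the convention favours retaining data over deleting it.

The LC error radii are deployment-specific in practice and are therefore
configuration, not constants. The shipped defaults are typical published
magnitudes, larger for the 1990s-era tags (B = 8 km) than for the modern
ones (B = 6 km used by the period-1 fixture vs 5–6 km for period 2; see
`lc_error_table()`).

### 1.3 Hourly interpolation

Filtered, corrected fixes are sampled by satellite passes, not by the
animal. They are therefore linearly interpolated (in the local projection)
onto the whole UTC hour grid. Gaps longer than 12 h are not interpolated at
all; interpolated points that land on shore are dropped; fix times off the
hour grid do not appear in the output. One consequence to keep in mind:
speeds and turning angles computed from interpolated positions are
*minimum* estimates, since the animal did not move in straight hourly
segments.

### 1.4 Habitat classes, ice types, movement metrics

Each hourly location gets two spatial metrics — distance to the nearest
coastline and to the nearest tidal glacier front, both in km — and exactly
one habitat class, assigned with strict precedence:

1. **Glacier-Fronts**: distance to the nearest front `< 5` km;
2. **Fjords**: inside a fjord polygon (and not rule 1);
3. **Coastal**: distance to the coast `< 5` km (and not rules 1–2);
4. **At-Sea**: everything else.

"Less than" is strict; a location at exactly 5.000 km falls through to the
next rule. The 5 km radius absorbs the combined Argos and shoreline-data
uncertainty and is configurable (`habitat_config()`). Fjord membership
requires explicit fjord polygons; the package does not attempt to infer
fjords from coastline concavity. Distance to coast is measured against the
full coastline including glacier-front segments (a
sensitivity variant would exclude them; the geometry layers make that a
caller-side filter).

Sea-ice types (Fast ice, Open Water, and four drift-ice concentration
bands) are joined from dated polygon fields: the field nearest in date is
used (ties to the earlier date), the first typed polygon containing the
point wins, and anything outside coverage is Open Water.

Movement metrics per hourly location: speed is the geodesic distance from
the previous location divided by elapsed time (m/s); the turning angle is
the unsigned deviation between incoming and outgoing headings in [0°, 180°]
(0 = dead ahead). The unsigned convention is the one consistent with
reported mean turning angles in the 40–55° range. Headings are computed in
a projection centred on the current point, so the metric is rotation
invariant; note that a track following a parallel of latitude at 78°N
genuinely turns by dlon·sin(lat) per step — that is geometry, not error.

The season index is whole days since the most recent 7 July (the earliest
tagging date in the motivating programme) and wraps at the *next* 7 July,
so December–January values continue past 150–210 instead of resetting.

## 2. Models

**Occupancy.** For each habitat class, the hourly indicator is modelled by
a binomial GAMM: a penalized thin-plate smooth of day-of-season per period
(period as a by-variable, basis dimension k = 10 by default, smoothness by
the fitter's internal PQL/REML criterion), an individual random intercept,
and an AR1 residual process within individual. The AR1 position variable is
the integer hour index, so correlation decays as ρ^gap across data gaps —
long gaps effectively break the chain. Period curves are compared by their
pointwise 95% bands (`bands_separate()`), mirroring
confidence-band-based model assessment rather than information criteria.
Fitted curves are returned on the probability scale on a day grid.

**Movement metrics.** Log speed and turning angle are modelled with
Gaussian linear mixed models: habitat × period fixed effects, individual
random intercept, within-individual AR1 (same hour-position convention).
Reference levels are Glacier-Fronts and the first period, so rows read as
contrasts against early-period glacier-front behaviour. Gaussian errors for
the turning angle are an admitted approximation (the metric lives on
[0, 180]); circular models are out of scope by design. p-values are
Wald-type with no multiplicity correction.

**Cell summaries.** Mean ± SD of speed and turn per habitat × period with a
seeded nonparametric bootstrap CI that resamples animals first, then each
chosen animal's locations — the animal is the sampling unit, locations are
serially dependent within it.

## 3. The synthetic world

Because the motivating telemetry is not public, the package ships a
generator for every input. It is a *stated world*, not a tuning dial: its
defaults encode the documented conditions (two tracking periods with
18 vs 16 males; record lengths drawn around 51 ± 31 vs 87 ± 52 days,
clipped to 2–163; sparser, noisier uplinks and an earlier freeze onset in
the early period; glacier fronts retreated landward in the recent period).

* `make_archipelago()` builds one elongated island whose west coast is cut
  by rectangular fjords, each capped by a glacier-front line; the epoch-2
  fronts sit `retreat_km` (default 5 km) deeper landward. Coastline
  vertices are spaced every 2 km and can be jittered; generation retries
  with halved jitter if a ring self-intersects.
* `simulate_tracks()` runs a four-state (one per habitat class)
  correlated random walk on the hourly grid: dwell-dominated Markov
  transitions, state-specific log-normal speeds and heading-change SDs
  (slow/tortuous at glacier fronts: 0.45 m/s, 70°; fast/directed in
  transit: 1.1 m/s, 18°), a pull toward the state's anchor geometry, and a
  seasonal hazard (default 0.02 h⁻¹ after the onset day) that pushes
  animals into the At-Sea state, emulating freeze-up. Steps that land
  ashore are redrawn up to 20 times, then reflected. The default
  transition matrix has stationary state occupancy ≈ (0.59, 0.17, 0.15,
  0.09) — glacier-front-dominated in the ice-free season, as observed.
* `observe_argos()` thins the true hourly path by an exponential-gap
  process (mean 3 h for period-1 tags, 1.5 h for period-2), draws an LC per
  fix from a class mix that is B-heavy (as marine-mammal Argos data are)
  and displaces the fix uniformly in its class's error disc (Z uses the B
  radius). With the shipped mixes and radii, 20–30% of raw fixes fall on
  land — the regime that makes the particle corrector necessary. This
  calibration is part of the stated world and was fixed before the
  acceptance measurements.
* `make_ice_fields()` grows crude but valid concentric ice bands (fast ice
  nearest shore, drift classes seaward) from the freeze-onset date, with
  coverage non-decreasing in time. They exercise the nearest-day and
  point-in-polygon logic; they are not oceanography.

What a green recovery test establishes: that the filtering–correction–
interpolation–classification chain recovers per-animal habitat time budgets
within serial-correlation-adjusted binomial error of the truth-replay
budgets, on a world with known truth. What it does not establish: realism
of currents, dive behaviour, tag failure modes, true Argos error shapes
(which are elliptical and heavy-tailed, not uniform discs), or shoreline
digitisation error.

## 4. Numerical and design notes

* **Geodesy in-package.** The environment provides no GIS stack, so the
  primitives are implemented here and tested against independent oracles:
  Vincenty distances against a numerically integrated meridian arc and a
  haversine bound; point-in-polygon against a winding-number oracle;
  segment distances against densified brute force; the projection
  round-trip against a 1 m bound at 500 km.
* **Determinism.** Every stochastic stage derives one RNG stream per animal
  from (global seed, animal id), so per-animal results are independent of
  batch composition, and the global RNG state is never touched. Identical
  config + seed ⇒ byte-identical outputs.
* **Effective sample size in recovery checks.** Hourly habitat indicators
  are strongly autocorrelated; recovery tolerances therefore use
  n_eff = n(1−ρ)/(1+ρ) with the lag-1 autocorrelation of the truth
  indicator, not the iid binomial n.
* **Radius→0 limit.** As LC radii shrink to zero the retained fixes equal
  truth exactly, but the hourly track retains between-fix interpolation
  error wherever the uplink process skipped hours; the RMS invariant is
  therefore monotonicity in the radius plus exactness at the fixes.
* **Duplicate uplink timestamps** keep the best LC (3 > 2 > 1 > A > B),
  then the first record — standard Argos practice.
* **Degenerate inputs.** All-Z tracks filter to empty with a warning;
  single-fix animals interpolate to nothing with a warning; a habitat
  indicator that never varies is a degenerate occupancy fit and errors
  with the habitat named; an empty habitat × period cell is a
  rank-deficiency error naming the cell.

## 5. Known limitations

Interpolated metrics are lower bounds on speed and turning. The SDA
maximal-retention formulation can differ from heuristic multi-pass filters
on pathological clusters of outliers (it retains more). Uniform-disc error
is a simplification of real Argos error ellipses. The occupancy GAMM uses
PQL, whose binomial fits are approximate; numerical equality with any
specific GAMM software is explicitly not a goal — behavioural equivalence
(curve shape, band separation) is what the tests assert.
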