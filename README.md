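# tideforage

Does the *tidal regime* — whether a coastal site is currently seeing one
high tide per day (diurnal) or two (semidiurnal) — predict how far a
central-place seabird forages from its colony, better than daily tidal
amplitude or date? Mixed tides switch between the two regimes in
roughly weekly runs as the diurnal constituents (K1, O1) beat against
the semidiurnal ones (M2, K2), and the two regimes can set up different
current structures, and hence different prey fields, over the foraging
grounds.

`tideforage` is an R package plus a scripted analysis that implements
the full chain from raw instrument records to that statistical
question, for penguin-style biologging data:

* **Tide regime classification** — high-tide detection (prominence- and
  separation-based peak criteria) and a per-day diurnal/semidiurnal
  label with daily amplitude `(max − min)/2`.
* **ARGOS track cleaning** — land masking and a sequential
  maximum-speed filter at the sustained swimming speed (8 km h⁻¹),
  with class-3 fixes immune.
* **Dive processing** — zero-offset correction of 1 Hz time–depth
  records (running quantile + morphological opening), detection of
  foraging dives (> 5 m, strict), and labeling of fixes within 150 s of
  a dive as diving locations.
* **Glider currents** — one 100 m depth-integrated current per
  inter-surfacing segment from the GPS-minus-dead-reckoning residual;
  Welch *t* on speeds, quadrant fractions, the Mardia–Watson–Wheeler
  uniform-scores test on bearings, a Watson U² von Mises
  goodness-of-fit with parametric bootstrap, and the wind–current
  correlation.
* **Foraging models** — trips segmented at 0.5 km colony returns, and
  random-intercept-per-trip linear mixed models of distance from the
  colony (DHI), fit by maximum likelihood:

  model 1: `DHI_ijk = β(regime_i) + b_j + ε_ijk`,  `b_j ~ N(0, σ_b²)`

  model 2 adds daily tidal amplitude and Julian day as fixed effects.
  The two are compared by a 2-df likelihood-ratio test and AIC.
* **Utilization mapping** — Gaussian-kernel density on a 725 m grid
  (σ = 1.5 km) about the colony and 95% utilization contour areas per
  regime.
* **A seeded synthetic-data generator** for all of the above (mixed
  tides, distance-model trips with class-dependent ARGOS error, drifting
  TDR records with ground truth, glider missions under a known current
  field, independent wind), so every stage is testable with no field
  data. See `vignettes/tideforage-methods.Rmd` for the model details and
  design choices.

## Worked example

The numbered scripts under `analysis/` run the study on a synthetic
28-day season (seed 1): `01_simulate.R` writes the raw CSV/GeoJSON set
under `results/raw/`, and stages 02–07 classify, filter, process dives,
estimate currents, and fit the models. Running them in order prints,
among other things:

```
$ Rscript analysis/02_tide_regimes.R
Season of 27 days: 13 diurnal, 12 semidiurnal, 2 unclassified
Regime runs: 2 d, 1 u, 2 d, 6 s, 6 d, 1 u, 1 d, 6 s, 2 d
Mean daily amplitude: 1.27 m (diurnal) vs 0.82 m (semidiurnal)

$ Rscript analysis/03_filter_tracks.R
720 fixes from 10 birds
  rejected on land:        37
  rejected by speed:      232
  retained:               451 (37.4% removed)

$ Rscript analysis/05_glider_currents.R
227 current estimates (132 diurnal, 95 semidiurnal)
mean speed 0.132 m/s; 0.144 (diurnal) vs 0.115 (semidiurnal): t = 3.02, d.f. = 205.67, p = 0.00287
bearing quadrants NE/SE/SW/NW: 78% / 9% / 7% / 6%
bearing distributions differ between regimes: W = 13.819, p = 0.000998 (permutation 0.0013)
von Mises fit to all bearings: U2 = 1.079, bootstrap p = 0.005
wind vs current speed: r = 0.010, t = 0.15, p = 0.88

$ Rscript analysis/07_full_pipeline.R
...
Diving locations: 5.0 km (diurnal) vs 10.0 km (semidiurnal) from the colony
regime effect (diving fixes): +4.89 km, t = 9.92, p = 3.4e-23
amplitude/Julian-day LRT (diving): chi2 = 2.34, p = 0.31
```

Reading the output: the season splits into week-scale regime runs;
diurnal episodes have the larger daily amplitude; depth-integrated
currents are stronger and more tightly northeast-directed during diurnal
tides (significant Welch *t* and Mardia–Watson–Wheeler *W*, while wind
explains nothing); and diving locations sit significantly farther from
the colony under semidiurnal tides, with the amplitude/Julian-day
extension adding nothing (non-significant 2-df LRT) — tidal regime alone
is the operative predictor in the simulated season, which is exactly the
structure the generator encodes.

The same machinery is available programmatically:

```r
library(tideforage)
report <- run_pipeline(pipeline_config(seed = 1))
report$models$eq1_diving$beta
report$utilization
```

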