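---
title: "Tidal regime switching and central-place foraging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tidal regime switching and central-place foraging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Mixed coastal tides do not oscillate between one and two high tides per
day on a daily rhythm: the diurnal constituents (K1, O1) beat against the
semidiurnal ones (M2, K2) on a fortnightly cycle, so a site sits in a
*diurnal regime* (one high tide per day) for several days to a week, then
switches to a *semidiurnal regime* (two highs), and back. For a
central-place forager such as a breeding penguin, the two regimes can
drive different current structures over the foraging grounds and hence
different prey fields. `tideforage` implements the full analysis chain
needed to ask whether tidal regime — rather than daily tidal amplitude or
date — predicts how far from the colony the birds forage: tide-gauge
classification, satellite-track cleaning, dive processing,
glider-derived current comparison, and mixed-effects modelling of
foraging distance, plus a seeded synthetic-data generator so the whole
chain is testable without access to field data.

## Tidal regime classification

A "high tide" is operationalized as a local maximum of the gauge series
with prominence of at least 0.1 m, with successive highs at least 8 h
apart (half-way between the ~12.4 h spacing of semidiurnal highs and the
~24 h spacing of diurnal highs; where two candidates fall closer, the
higher is kept). Days are bounded in station-local time (a configurable
UTC offset, default -3 h) and labeled diurnal with exactly one high,
semidiurnal with two or more, and unclassified with none (gauge gaps or
detection dropouts at regime transitions; fixes on such days drop out of
the models). Daily amplitude is half the day's range, (max - min) / 2.

The per-day rule makes the "time periods" of the analysis contiguous runs
of same-labeled days; marginal days at regime transitions can flip under
observation noise, because the secondary high's prominence passes through
the 0.1 m threshold continuously. With millimetre-accurate modern gauge
records this affects at most the single day at a transition.

## Track filtering

ARGOS fixes carry quality classes 3, 2, 1 (stated accuracies within
100 m, 250 m, 500-1500 m) and 0, A, B (no error estimate). Cleaning is
two mechanical steps: fixes strictly inside a land polygon are rejected
(even-odd rule; boundary points are kept), then a sequential maximum-speed
filter enforces a sustained-swimming-speed ceiling of 8 km/h. The filter
is greedy: while any consecutive pair of retained fixes implies a speed
over the ceiling, the fix involved in a violation whose implied speed
(the larger of the speeds to its retained neighbours) is greatest is
dropped. Ties on that criterion are broken by the *smaller* neighbour
speed — an isolated spike has two fast neighbour speeds while its
innocent neighbour has one — and finally by preferring the later fix.
Class 3 fixes and the first and last fix of a track are never removed.
The rule is deterministic, idempotent, and checked in the tests against
an independent brute-force implementation. A per-fix manual-rejection
list is honoured in place of interactive visual inspection of class B
fixes.

## Dive records

Time-depth recorders drift, so a 1 Hz depth series is zero-offset
corrected before dive detection: a centered running 5% quantile over
120 s tracks the surface reading through dives (any dive shorter than
~95% of the window leaves the quantile at the surface level), and a
morphological opening (running minimum then running maximum, both over
1800 s) removes the positive bias the quantile picks up inside longer
dives. The opening follows monotone drift *exactly* — a plain running
minimum, by contrast, lags a rising baseline by half its window, which
at a typical 0.01 m/min drift is a 0.15 m standing error. Both window
lengths are configurable; the defaults span surface intervals but not
full foraging bouts.

Dives are maximal runs of samples strictly deeper than 5 m (an excursion
to exactly 5.0 m is not a dive). A location fix is a *diving location* if
its time is within 150 s, inclusive, of the nearest point of any dive
interval — measured to the interval, not to the dive start, so a fix
during a long dive has gap zero.

## Depth-integrated currents from glider dead reckoning

Each inter-surfacing segment of a buoyancy glider yields one 100 m
depth-integrated current estimate: the displacement from the
dead-reckoned surfacing position to the GPS surfacing position, divided
by the segment duration. Displacements are taken on a local tangent
plane (equirectangular with cosine-latitude scaling) at the segment
midpoint; at segment scales of a few kilometres the spherical correction
is far below the GPS noise floor. Bearings follow the oceanographic
"direction toward" convention, clockwise from true north, and quadrant
fractions use NE = [0, 90), SE = [90, 180), SW = [180, 270),
NW = [270, 360). Segments spanning a regime switch are labeled by their
midpoint time.

Speeds between regimes are compared with a Welch two-sample t-test
(unequal variances, fractional degrees of freedom); wind is related to
current speed by a plain Pearson correlation with its t-test.

## Circular statistics

Bearing distributions are compared with the Mardia-Watson-Wheeler
uniform-scores test: pool the two samples, rank them around the circle,
map rank k to the uniform score 2*pi*k/N (ties receive averaged ranks),
and form W = 2 * sum_i (C_i^2 + S_i^2) / n_i from the per-sample
resultants of the scores. W is asymptotically chi-squared with 2 df
under the null; a permutation p-value is available, computed exhaustively
whenever the number of label assignments fits the permutation budget and
by seeded resampling (with the add-one estimator) otherwise. W is
invariant under common rotation of all angles, and the asymptotic test
holds its 5% level to within Monte-Carlo error at n1 = n2 = 30 (checked
over 5000 simulated nulls in the test suite).

The nonparametric route is justified by a Watson U-squared goodness-of-fit
test against a fitted von Mises distribution: kappa is obtained by
Newton inversion of the mean-resultant-length equation A1(kappa) = Rbar
(standard small/large-R starting series, tolerance 1e-10, scaled Bessel
ratios so large kappa cannot overflow), and the p-value comes from a
seeded parametric bootstrap that refits the parameters on every
replicate, so the estimation step is properly accounted for.

## Foraging-distance models

Trips are maximal runs of fixes farther than 0.5 km from the colony,
bounded by returns to within 0.5 km; boundary fixes are excluded from
trips (and hence from the models), and leading/trailing runs without a
bounding return are kept but flagged open. Each fix carries its distance
to the colony, the day's regime and daily amplitude (the daily value,
not the instantaneous height, consistent with reporting regime-mean
amplitudes), and the Julian day in station-local time.

Two Gaussian mixed models with a random intercept per trip are fit by
maximum likelihood (not REML, so AIC is comparable across fixed-effect
structures): regime as the only fixed effect, and regime plus daily
amplitude plus Julian day. The random intercept absorbs the strong
within-trip spatial autocorrelation of consecutive fixes. Wald t
statistics use a normal approximation for p-values; finite-sample
degrees-of-freedom corrections (Satterthwaite and kin) are deliberately
out of scope. AIC counts the fixed effects plus the two variance
parameters. Nested fits are compared by the likelihood-ratio statistic
2*(logLik_big - logLik_small) on the difference in fixed-effect count,
and by the AIC difference with the conventional "within 2" rule: the
smaller model is preferred unless the larger beats it by more than 2.
Residual normality is checked with Shapiro-Wilk (Anderson-Darling past
its n = 5000 implementation limit). If a simulated dataset is fit
perfectly by the fixed effects (a noiseless generator run), the model is
degenerate and the fit reports the least-squares coefficients with both
variances zero rather than a spurious lme4 fit.

## Utilization contours

Locations are projected to an azimuthal-equidistant plane about the
colony and smoothed with an isotropic Gaussian kernel on a 725 m grid.
The kernel's "~3 km size" is read as a diameter, giving sigma = 1.5 km
(configurable). The grid is padded by four kernel SDs so the density
integrates to one (to 0.01, with automatic expansion otherwise).

The 95% contour is, by default, the standard utilization-distribution
*volume* contour: the smallest-density threshold whose super-level set
holds 95% of the integrated density. For kernel surfaces this region
contains approximately 95% of the observations, and for Gaussian data its
area has the closed form pi * (sigma^2 + h^2) * chi2_95(2 df) — the
bandwidth inflates the mapped range, as it should for a smoothed
utilization map, and a point cluster much tighter than the kernel tends
to the single-kernel disk pi * h^2 * chi2_95. An alternative rule,
`method = "observations"`, thresholds at the 5th percentile of the
density evaluated at the observation points, so the contour contains
exactly 95% of the sample; its area tracks the raw sample spread
(pi * sigma^2 * chi2_95 for Gaussian data) with no bandwidth term, and it
degenerates for clusters smaller than a grid cell. The volume rule is the
default because it is the field's standard home-range contour and the one
whose closed-form behaviour the area checks in the test suite verify;
both rules are exposed.

## The synthetic season

The generator emulates the statistical structure the analysis assumes,
not the mechanics of swimming birds:

* **Tides.** Harmonic sums over K1/O1/M2/K2 with defaults (0.61, 0.55,
  0.45, 0.15 m; phases 0, 0, 1.2, 0.5 rad) chosen so a ~4-week season
  splits roughly evenly between regimes in multi-day runs, with daily
  amplitudes near 1.27 m (diurnal episodes) and 0.82 m (semidiurnal) —
  a mixed, mainly diurnal tide with a form factor near 2. Gauge noise
  defaults to 2 mm in the pipeline: modern gauges are millimetre-level,
  and decimetre noise would artificially flip marginal regime days by
  inflating secondary-peak prominence.
* **Trips.** One trip per calendar day, cycled over ~n/3 birds; per-fix
  true distance is beta(regime) + b_trip + eps with defaults
  beta = 5.4/9.1 km, sigma_trip = 1.4 km, sigma_resid = 2 km, truncated
  below at 0.6 km so foraging fixes stay outside the colony-return
  radius (the truncation moves regime means by ~0.02 km, well inside
  every tolerance used). Fix spacing (default 30 min) is configuration,
  since real tags vary. Positions are placed by exact spherical geometry
  at a drawn bearing. This is deliberately *not* a movement model: there
  is no autocorrelated path within a trip beyond the shared trip
  intercept and heading.
* **ARGOS error.** Classes 3/2/1 get bivariate-normal error scaled so
  97.5% of radial errors fall within the stated class accuracy
  (100/250/1000 m); classes 0/A/B, which carry no stated accuracy, get
  heavy-tailed t(3) errors with 1.5/3/10 km scales. A configurable
  fraction of fixes (5% in the pipeline) is displaced onto the land
  polygon to exercise masking. The class mix and the heavy tails are the
  main driver of the filter-removal fraction, which is reported, not
  targeted.
* **Dive records.** Square dives at known times on a linear drift plus
  2-5 cm noise, with the ground-truth dive log attached, so correction
  and detection are scored against truth.
* **Glider.** The mission is integrated on a planar local grid at 60 s
  steps; the vehicle navigates on its dead-reckoned position and is
  advected by a deterministic current field tied to the regime calendar
  (steady, never-reversing flow along the principal axis on diurnal
  days; an M2-period oscillation with reversals on semidiurnal days;
  small incommensurate sinusoids spread the bearings). Segment endpoint
  pairs are written back to latitude/longitude on their own local
  tangent plane — the frame in which a dead-reckoning residual is
  defined — so the estimator's recovery can be verified to 1e-6 m/s
  rather than being limited by projection distortion.
* **Wind.** Independent truncated-normal speeds, so the wind-current
  correlation is null by construction.

What passing tests on these data do *not* show: robustness to real
movement autocorrelation within trips, to non-square dive profiles, to
spatially varying currents across the glider track, or to ARGOS error
distributions beyond the assumed families. The generator shares the
package's geodesy primitives (a deliberate choice — those primitives are
themselves tested against closed forms and an independent library), but
every statistical stage is checked against independent oracles: brute
force re-implementations, exhaustive enumeration, direct likelihood
maximisation, and closed-form Gaussian results.

One known artifact is worth naming: the generator draws distances on the
identity scale (the structure of the regime-only model), so the
log10-transformed variant of the model — included because real
all-location records are right-skewed — is misspecified by construction
on synthetic data (a log of a truncated normal), and its
likelihood-ratio test against the amplitude/Julian-day extension can
reject spuriously in some seasons. The calibration checks for the model
comparison therefore run on the identity scale, where the generator and
the model agree.

## Numerical choices

* Haversine distances on a sphere of radius 6371.0088 km; azimuthal
  equidistant projection about the colony for mapping.
* Peak detection: strict local maxima, standard prominence (height above
  the higher of the two key saddles), separation enforced
  highest-first.
* Running filters are compiled: the running quantile is O(n w) with
  per-window selection, the running min/max are O(n) monotonic deques;
  windows shrink symmetrically at the series edges.
* kappa inversion: Newton with analytic derivative
  1 - A1/kappa - A1^2, halving steps that would leave the domain,
  capped at 1e5.
* Degenerate inputs are first-class: constant tide series (no highs),
  all-identical angles (warned, p = 1), zero-variance speed groups
  (error unless means agree), perfect-fit mixed models (degenerate
  result), empty dive lists, fixes exactly on polygon boundaries
  (retained).

## Problem sizes

The shipped test-and-verification sizes are chosen to make every check
statistically meaningful at desk scale: a 28-day season with 30 trips of
22 fixes; 5000-replicate null calibration of the Mardia-Watson-Wheeler
test at n1 = n2 = 30; 200-replicate recovery and type-I studies of the
regime model at 30 trips; a 500-replicate calibration of the 2-df model
comparison at 60 trips of 8 fixes (the larger trip count keeps the
likelihood-ratio asymptotics honest for between-trip covariates);
5000-point Gaussian clouds for contour-area closed forms; and 20-day
glider missions at 2 h surfacings for current recovery.

## Limitations

Beyond the generator caveats above: the speed filter implements the
speed criterion only (no turning-angle test); p-values for fixed effects
use the normal approximation; currents are depth-integrated only, with
no flight-model correction; and the regime classifier is as good as its
peak criteria — sites with shallow mixed tides near the prominence
threshold would need site-specific tuning of the 0.1 m / 8 h defaults.
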