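---
title: "Detecting area-restricted search and its oceanographic drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting area-restricted search and its oceanographic drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trackars)
```

`trackars` analyses high-frequency GPS tracks of central-place foraging
seabirds: where along a trip did the bird concentrate its search, at what
spatial scales, and which oceanographic conditions predict those places.
This vignette explains the models and the choices behind them; the README
shows a worked run.

## From raw fixes to bird-days

Tags record a fix every 10–100 s. Processing assumes a single colony as
the central place and proceeds per bird:

- **Projection.** Fixes are projected to planar metres with a local
  azimuthal-equidistant projection centred on the colony, rather than a
  fixed UTM zone. Within a foraging range of a few hundred km the
  distortion is far below 0.1 %, and the colony is always the origin,
  which simplifies every later step. The inverse projection round-trips
  within 1 m (tested).
- **Speed filter.** Any fix implying a ground speed above 90 km/h
  relative to its predecessor is removed — the later fix of the violating
  pair — and speeds are recomputed after each removal until none remains.
  This mirrors how transmission glitches appear in practice: a single
  displaced fix produces two successive violations.
- **Trips.** A trip is a maximal excursion beyond a colony buffer,
  extended by the fix immediately before departure and immediately after
  return. The buffer radius is 1 km by default: the colony islet is only
  ~0.5 km², so 1 km separates attendance from transit without clipping
  near-colony flight. Fixes that never leave the buffer are colony
  attendance, not trips.
- **Night rest and bird-days.** Birds that stay out overnight drift on
  the water. A rest bout is a maximal run of fixes during local night
  (solar 20:00–05:00 at the colony longitude) with all speeds below
  2 km/h, lasting at least 1 h. Rest fixes are removed and the remaining
  at-sea stretches become bird-days — the unit of all further analysis,
  because prey fields and the biological role of a trip can change
  overnight. This rule is deliberately simple (a clock window plus a speed
  ceiling) rather than a behavioural classifier; it is exact on the
  synthetic data and transparent on real data.
- **Interpolation.** Each bird-day is resampled at exactly 100 m of arc
  length along the planar polyline, with timestamps interpolated linearly
  within each original segment. 100-m spacing standardises tracks
  recorded at different fix rates and is what the first-passage-time
  machinery expects. Points lie on the original polyline; the final point
  is the original endpoint and may close a shorter step. Note the chord
  between two consecutive interpolated points can be slightly shorter
  than 100 m where the path turns; arc spacing, not chord spacing, is the
  invariant.

## First-passage time and ARS scales

The first-passage time at location *i* and radius *r* is the time the
bird takes to cross a circle of radius *r* centred at *i*, walking the
track forward plus backward from *i*. Exits are located by exact
segment–circle intersection with linear time interpolation, not by
resampling; a dense-resampling brute force agrees to better than 1e-6
relative error (tested). Where the track ends inside the circle in either
direction the FPT is undefined and the location is excluded from that
radius's statistics — the convention of the FPT literature for track
boundaries.

Slow, tortuous search inflates FPT; the variance of log FPT across a
bird-day's locations, as a function of *r*, peaks at the characteristic
scales of that search. The scan uses radii from 10 m (the approximate GPS
accuracy) to half the mean colony distance, in 10-m increments by default
(`r_step` trades resolution for time; 50–100 m loses little above a few
hundred metres). Peak picking applies:

- a 5-bin moving average (raw variance curves jitter at the radius-grid
  scale);
- a prominence floor of 5 % of the smoothed curve's range (suppresses
  shoulder artefacts);
- a coverage requirement that at least 50 % of locations have defined FPT
  at the radius (boundary-dominated radii are unreliable);
- curve endpoints are not maxima (a monotone large-scale trend is not a
  scale).

Several nested scales per day are common; summaries record their number
and the smallest and largest. Fine-scale analysis keeps only the smallest
scale at or below 8 km — larger peaks reflect mesoscale behaviour rather
than targeted prey capture. A day may legitimately have no fine scale.

The variance-peak radius overestimates the physical patch radius by
roughly 1.5x (a 1-km simulated patch peaks near 1.4–1.7 km): the circle
must be somewhat larger than the patch before crossing it separates
searching from commuting cleanly. Recovery experiments therefore accept a
[0.5, 2] x patch-radius window, and parameter-recovery guarantees are
stated within a factor of two.

## Labelling ARS locations

At the chosen radius, the per-location log FPT series is partitioned by
Lavielle's penalized-contrast method: an exact dynamic program minimises
the within-segment sum of squares for every candidate segment count
K = 1..20, with segments of at least `Lmin = 5` locations. The DP is
exact — it reproduces exhaustive enumeration (tested) — so the only
modelling freedom is the choice of K. The contrast J(K) is scaled so that
its total decrease over K ∈ [1, Kmax] averages 1 per added segment, and
the chosen K is the largest whose decrease still exceeds `S = 0.75`.
(A literal scaling of J to [0, 1] would make every decrease sum to 1 and
the 0.75 threshold reachable only at K = 2, contradicting the K ∈ [2, 20]
contract, so the standard normalisation is used.) If no K qualifies the
series stays one segment, which downstream yields zero ARS — the right
answer for a featureless day. Series shorter than `2*Lmin` fall back to a
single segment with a message.

Segments whose mean log FPT strictly exceeds the day's overall mean are
ARS; ties are non-ARS (strict inequality, so a constant series labels
nothing). Locations with undefined FPT at the chosen radius are non-ARS;
interior gaps in the series (rare) are bridged by linear interpolation
before segmenting. Contiguous ARS runs form zones, with per-day metrics:
zone count, summed duration, summed path length, mean colony distance and
the circular mean of colony-to-ARS bearings (bearings are circular —
means are taken on the unit circle, and for multivariate analyses angles
enter as sine/cosine pairs).

## Environmental annotation

Eleven covariates on regular lon/lat grids are attached to every
interpolated location by bilinear interpolation (exact at nodes,
continuous across cell edges; a query with any masked neighbour is
missing). Grids are sampled at native resolution — no re-gridding, so
each variable contributes at the finest scale available. Bilinear was
chosen over nearest-neighbour for all variables including bathymetry
because the source material says only "linearly interpolated";
nearest-neighbour would introduce spurious step edges at cell boundaries.

Time-stacked grids are matched by nearest layer within half the product
cadence (6 h for 6-hourly wind, 12 h daily, 4 d for 8-day, 15 d monthly;
ties go to the earlier layer). By default the synthetic generator emits
static fields per sampling period, so matching only matters for
user-supplied stacks.

Distance to the nearest SST front is the great-circle distance to the
centre of the nearest cell whose front probability exceeds a threshold
(default: any positive probability — the cut-off its upstream product
used is not documented, so it is exposed as a parameter), 0 km if the
location's own cell is frontal. This distance replaces the raw front
probability in the predictor set.

## Behaviour statistics

Trip descriptors (duration, path length, maximum colony distance,
smallest/largest ARS scale) and small-scale ARS characteristics are
compared across sex, nest stage, sampling period and sex x stage:

- **Distance.** Euclidean distance on z-scored metrics (Gower available).
  Without standardisation the km-scale variables would dominate counts
  and hours.
- **NMDS** via `vegan::metaMDS` for ordination and its stress value.
- **perMANOVA.** One-factor pseudo-F from among/within sums of squared
  distances with `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)` (10 000
  permutations by default; the smallest attainable p is 1/(n_perm+1)).
  The statistic matches `vegan::adonis2` (tested); the in-package
  implementation exists so tiny designs can be enumerated exactly.
  Post-hoc pairwise comparisons use Holm correction.
- **Dispersion.** Distances to the group's *spatial median* in
  principal-coordinate space (`vegan::betadisper(type = "median")`),
  compared by a permutation F test. The centroid variant is
  anticonservative at small groups (type-I error near 0.10 at three
  groups of eight in our null simulations) while the median variant is
  calibrated; this is also why spatial medians are the published default
  for the test.
- **Trip-type proportions** use Pearson chi-squared without continuity
  correction.

Permutation seeds are explicit arguments; fixed seeds give reproducible
p-values. One practical caution encoded in the tests: when simulating
calibration experiments, draw all datasets before running any
permutation tests — generating the next dataset from the RNG stream that
just produced another replicate's permutations couples the replicates
and distorts the measured rejection rate.

## Per-day habitat forests

Each bird-day with both classes present gets its own classification
forest of ARS vs non-ARS on the 11 covariates. Day-level models are the
point: the relationship between search and environment is allowed to
differ every day, and only the importance profiles are aggregated.

- 1000 trees; each tree trains on an independent random two-thirds of the
  day's locations drawn **without** replacement and is validated on its
  held-out third. (Classical bagging resamples with replacement;
  two-thirds-without-replacement is the described design and is the
  package default, with `train_frac` exposed.)
- `mtry = 3` predictors per node (the square root of 11), Gini splits,
  growth to purity or nodes of at most 5 locations.
- Validation sensitivity/specificity/accuracy aggregate by **vote**: each
  location is predicted by the majority of the trees that did not train
  on it. Averaging per-tree confusion rates instead caps near 0.90 on a
  perfectly separable day (single trees with mtry = 3 waste splits on
  noise), which we confirmed independently with scikit-learn decision
  trees on the same design; vote aggregation reaches ~0.99, the level a
  whole-model validation describes.
- Raw importance is the impurity decrease summed over splits and averaged
  over trees, standardized per day to sum to 100 % — so days are
  comparable regardless of length, and "uninformative" sits at
  100/11 ≈ 9.1 %.
- Spatial autocorrelation between consecutive 100-m locations is *not*
  corrected — deliberately, to keep the estimator faithful to the
  field-standard design. Within a day, any smooth field can partly
  separate one patch from commute; this confounding is real and is why
  day-level importances are noisy and only the cross-day aggregate is
  interpreted.

Because tracking effort is uneven, population importance is a stratified
bootstrap: each of 1000 iterations draws one bird-day per trip per bird
(one per bird in per-period analyses), averages the day profiles, and the
summary is the mean and SD over iterations; every iteration mean sums to
100 by construction. Partial dependence evaluates the ensemble's mean
predicted ARS probability with one covariate forced across a 50-point
quantile grid of its observed range; curves from many days are pooled and
smoothed with a penalized spline (`mgcv::gam`, basis dimension capped by
the number of distinct grid values) with a pointwise 95 % band. A single
curve passes through unchanged. A reporting utility tallies how often
each variable exceeds the 75th percentile of all day-level importances.

## The synthetic world

`simulate_study()` generates the conditions of a 135-bird colony study:
1–9 trips per bird with a decaying profile averaging ~2.2; trip lengths of
1/2/3 days with probabilities 0.67/0.30/0.03; fix intervals drawn from
{10, 33, 50, 100} s per bird; commuting flight at 10.5 m/s (~38 km/h);
planned maximum trip distances log-uniform over 30–120 km; colony at
(-89.7, 22.4). Movement alternates directed commutes (heading noise
~5°) with ARS bouts: a confined random walk with wide turning angles
whose steps are redirected inward at 90 % of the patch radius, so bout
fixes stay within the patch. Nested configurations embed several small
bouts, scattered across the outer region at 40–90 % of its radius and
connected by full-speed transits, inside one large slow-search region —
this makes the track genuinely tortuous at both scales, which is what
nested variance peaks require. Bouts are dispersed along and around the
outbound direction (bearing jitter ±40°) so that no single smooth
environmental field can mimic a consistent driver across a day's patches.
Multi-day trips wander until local evening, drift at ≤0.5 km/h overnight,
and return to the colony on the final day; patch centres and wander
waypoints keep clear of the colony buffer so a multi-day trip is never
split in two by the trip splitter.

GPS error is AR(1) with 10-m stationary sd, decorrelating over ~15
minutes. White 10-m jitter would be wrong at 10-s fix intervals: it fakes
km/h-scale apparent speeds all night and breaks any rest rule, whereas
real logger error is strongly autocorrelated between consecutive fixes.

Environmental fields: each covariate is a smoothed random field scaled to
its observed range (correlation length ~0.15°). Driver variables (by
default SSHA with band 0.0–0.1 m and current velocity with band
0.05–0.1 m/s) sit exactly at their band midpoint inside every patch
footprint (plateau to 1.0 r, linear taper to 1.3 r) and avoid the band by
a 10 %-of-range margin elsewhere; with zero noise the value at a patch
centre is exactly the midpoint. Fronts are short arcs placed through the
centres of a 4 x 4 partition of the domain, which bounds every point's
distance-to-front by about 100 km, inside the observed 0–142 km range.
The generator emits 12 grids: 10 scalar covariates, a precomputed
`dist_front` grid, and the `front_probability` grid it derives from.

What a green test establishes — and what it does not: the synthetic world
has piecewise-stationary behaviour, exactly circular patches, stationary
fields with a designed driver signal, and noise-free labels in its truth
record. Real tracks have gradual behavioural transitions, moving prey,
collinear and temporally varying environments, and no ground truth.
Passing the recovery tests shows the estimators are correct and
well-calibrated under their stated assumptions; it does not certify
effect sizes on real data.

## Degenerate inputs and numerical conventions

- Tracks that never leave the buffer yield zero trips (not an error);
  bird-days shorter than 50 interpolated locations are dropped with a
  message; zero-length paths refuse interpolation.
- All locations at the colony make the FPT scan radius degenerate →
  error.
- FPT is discontinuous where the path is exactly tangent to a circle;
  under last-ulp coordinate perturbations (e.g. a rotated frame) isolated
  locations can flip to a later crossing. Invariance tests therefore
  compare all-but-a-fraction of entries tightly rather than demanding
  bitwise equality.
- `standardize_importance` refuses all-zero importances; single-class
  days are excluded from designs with a message.
- Chi-squared warns on expected cell counts below 1; tables with an
  all-zero margin are errors.
- Every stochastic function takes a seed argument; a fixed
  `sim_config(seed=)` makes the whole study byte-identical.

## Limitations

- The night-rest rule is a heuristic; birds resting through dawn, or
  drifting faster than 2 km/h in current, would be mis-kept.
- One colony per study; no multi-colony support.
- perMANOVA is one-factor (with pairwise post-hocs); no interaction
  pseudo-F in the strict multi-factor sense — the sex x stage interaction
  is handled as a four-level factor.
- The forest offers no spatial block subsampling; importance on real
  tracks inherits the autocorrelation optimism discussed above.
- NetCDF rasters are not read directly; convert to the long-format CSV
  grid (`lon,lat[,time],value`) accepted by `read_raster_csv()`.
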