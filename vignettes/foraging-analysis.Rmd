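---
title: "Land or sea: models and methods behind gullforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land or sea: models and methods behind gullforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gullforage)
```

## The scientific problem

Breeding gulls are central-place foragers: every feeding excursion starts and
ends at the nest. An omnivorous species can spend that excursion at sea or on
agricultural land, and the balance between the two shifts with time of day,
weather, and the demands of the breeding cycle — while individual birds may
hold strongly to one strategy. This package turns raw GPS fixes into
per-trip habitat summaries and fits the statistical models that quantify
those effects.

## From fixes to trips to a response

**Segmentation.** A trip opens at the first fix beyond 500 m of the nest
following a fix within it, and closes symmetrically. We take the departure
instant as the midpoint of the bracketing inside/outside fix pair: under
regular sampling the true crossing is uniformly distributed between the two
fixes, so the midpoint is unbiased and its error is bounded by half the
sampling interval (150 s at 300 s sampling — negligible against multi-hour
trips). Trips still open when a track ends have no defined return and are
excluded by default.

**Filtering.** Analysis trips must be complete, at least 30 min long, reach
at least 3 km from the colony, contain at least 5 raw fixes, have no internal
gap longer than half their duration, and depart inside the 20 May – 21 July
focal window (extendable to 30 April for pre-laying). All thresholds sit in
`filter_config()` and every exclusion is logged with its reason, so the
counts entering the models are auditable.

**The response.** Trip fixes are linearly interpolated onto a regular 300 s
grid first, so that each point represents an equal slice of time and a
per-point proportion reads as a time proportion. A grid point is a likely
foraging point iff its speed lies in `[0, 4]` m/s and it is at least 3 km
from the colony. The lower/upper speed pair brackets walking, swimming and
area-restricted search from below the flapping-flight range (gull commuting
flight is 8–13 m/s; 4 m/s separates the two modes cleanly at 300 s
sampling); the colony-distance rule removes nest attendance and loafing.
Both thresholds are explicit arguments — they are the least certain numbers
in the pipeline and deserve sensitivity checks. Each foraging point is land
or sea by a boundary-inclusive point-in-polygon test (a bird on the
waterline is on land; any one consistent rule would do, but it must be one
rule). The trip response is the land proportion `p_land`, displayed in three
classes: sea (< 5%), mixed (5–95%), land (> 95%). The printed bounds are
strict inequalities, so exact 0.05 and 0.95 resolve to mixed. Trips with no
foraging points are *unclassified* and drop out of the proportion models.

**Covariates.** Sunrise proximity is `cos(pi * t / 12)` of the signed hours
`t` to the nearest sunrise (1 at sunrise, 0 at ±6 h, −1 at 12 h). Using the
*nearest* sunrise wraps `t` into `(−12, 12]` and treats pre-dawn departures
symmetrically; hours-since-last-sunrise in `[0, 24)` would reproduce the
same anchor values, and the cosine makes the two readings equivalent.
Sunrise itself comes from the NOAA solar-position equations (sun centre at
−0.833°), iterated so the solar coefficients are evaluated at the event
time; mid-latitude accuracy is well under two minutes, far inside the 300 s
sampling noise. Weather summaries interpolate the colony series to the
departure instant and 6, 12 and 18 h before it, then average (sum for
precipitation rate, giving cumulative pre-departure rainfall). Breeding
stages are fixed calendar windows applied per year; sex uses the colony's
113.5 mm head+bill discriminant, with exactly 113.5 mm treated as
indeterminate rather than silently assigned.

## The mixed model

The per-trip counts are modelled binomially:

$$ y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
   \mathrm{logit}(p_i) = x_i^\top \beta + u_{j(i)}, \qquad
   u_j \sim N(0, \sigma^2_\alpha), $$

with `y` the land foraging points, `n` all foraging points of the trip, and
`u` the per-individual intercept (for the field surveys, a Bernoulli
response with field-within-transect nested intercepts
`u_transect + u_field`). Modelling the proportion with its point count as
the binomial denominator weights trips by the time they actually spent
foraging; trips with no foraging points have no denominator and are
excluded, which is also why the model's row count is slightly below the trip
count.

**Estimation.** The marginal likelihood integrates over `u`; we maximize its
Laplace approximation. The inner penalized problem (the conditional mode of
`u`) is solved by damped Newton iterations — a closed-form diagonal solve
for a single grouping factor, a dense solve for nested intercepts — to a
gradient norm of 1e-8, and contributes
$-\tfrac12 \log\det(I + \sigma^2 Z^\top W Z)$ to the log-likelihood. The
outer problem optimizes `(beta, sigma)` by bounded quasi-Newton, with the
variance parameter on the SD scale bounded below by zero: the profile is
smooth there, whereas on the log scale it flattens as `sigma -> 0` and
stalls the optimizer exactly in the null fits that permutation tests spend
most of their time on. Starting values come from the no-random-effect
logistic fit; a non-converged run is restarted once from its own solution
before being flagged. For single-grouping models an adaptive Gauss–Hermite
mode (≥ 9 nodes, scaled and centred at each group's conditional mode) is
available as a verification target; on all our fixtures it agrees with the
Laplace log-likelihood to well under 0.1.

**Toolkit.** AICc is `-2ℓ + 2k + 2k(k+1)/(n−k−1)` with `k` counting fixed
coefficients *and* variance components — the convention must be fixed one
way for rankings to be self-consistent, and counting estimated variance
parameters errs on the honest side. R² follows the latent-scale variance
partition with the logistic distribution-specific variance `pi^2/3`.
Standardization centres numeric predictors and divides by two standard
deviations (binary predictors are centred only), making coefficients
directly comparable. Collinearity is the exact 2-norm condition number of
the design including the intercept. Single-term deletions respect
marginality (a main effect inside a retained interaction is not droppable)
and compare full and reduced Laplace log-likelihoods by chi-square.

**Repeatability.** The adjusted latent-scale repeatability is
`r = sigma^2_alpha / (sigma^2_alpha + pi^2/3)`, computed from the
standardized best model so fixed effects are accounted for. Latent scale is
the one choice the variance decomposition makes exact for a logit link; an
observation-scale `r` could be simulated from the fitted model, but its
value depends on the covariate distribution and trial sizes, so we report
the latent one. The permutation test shuffles individual labels across
trips and refits (plus-one rule, so `p` floors at `1/(n+1)` and is never
zero); the parametric bootstrap simulates new responses from the fitted
model — fresh intercepts, binomial noise at the observed trial counts —
refits, and takes the percentile interval. Percentile intervals inherit the
ML variance component's small-sample downward bias; at the study's
information level (19 individuals, tens of trips each, tens of points per
trip) the simulated coverage in our tests is ~90% for a nominal 95%, and
markedly worse for much smaller designs — a caveat worth keeping in mind
when transferring the method.

## The synthetic study generator

The generator exists so that every stage above is testable against known
ground truth. `scenario_s1()` encodes the study conditions: 19 individuals,
three seasons, ~1038 trips in the focal window at 300 s sampling with
occasional gaps; a classified-trip mixture of 21.5/9.1/69.4%
land/mixed/sea plus a 1.35% unclassified rate; class-wise lognormal
durations (medians 6.2/3.9/11.3 h for land/sea/mixed) and maximum distances
(20.8/23.2/39.3 km), parameterized by quartile matching
(`sdlog = (ln q75 − ln q25)/(2·0.6745)`) — positive, right-skewed, and fully
determined by printed medians and IQRs; and a between-individual propensity
SD of 3.79, the value at which the latent repeatability
`sigma^2/(sigma^2 + pi^2/3)` equals 0.814.

Each trip's latent land propensity is
`eta = a_ind + 1.0·sunrise_prox + 0.4·z(cloud) − 0.4·z(temp) + 0.7·logistic`,
with the weather terms taken from the same 24 h summaries the annotation
stage computes. Classes come from empirical-quantile thresholds on `eta`
(an ordered-threshold reading of the class mixture): individuals with high
intercepts do land trips with much higher probability, yet the realized
classified mixture matches the configured one for every seed. The
individual intercepts are drawn stratified (one draw per probability
stratum, standardized to the exact configured SD): with only 19 individuals,
plain i.i.d. draws would make the realized study mixture swing by many
percentage points from seed to seed, which would say nothing about the
pipeline being tested.

Rendering turns each trip into commute fixes (≈10 m/s) toward a foraging
site — east onto the mainland for land trips, west over open water for sea
trips, both for mixed trips with the drawn land share — plus slow foraging
fixes jittering around the site, on the sampling grid with geometric gaps.
Two small design points matter downstream. First, trips are not perfectly
pure: 12% of pure-class trips include one short opposite-habitat bout
(gated to trips with enough foraging time that the bout stays under the 5%
class bound). Without it, several individuals would have *no*
opposite-habitat points at all, their pooled land fraction would sit exactly
at 0 or 1, and the refitted variance component would diverge — real
classification always has a little noise, and the model needs it. Second,
unclassified trips are rendered as a dwell-free commuting triangle whose
bends stay under 90°, because any out-and-back route produces one slow
interpolated fix at the turning point, which would silently turn an
unclassified trip into a sea trip. The two free noise knobs
(`trip_noise_scale = 0.7`, `impurity_rate = 0.12`) were calibrated once, at
design time, so that the full pipeline run reproduces the encoded study
statistics — the class mixture, the pooled median duration near 4.8 h, and
a refitted repeatability near 0.814 — and then frozen.

What the generator does *not* emulate: real coastlines (two polygons stand
in for an island-and-mainland geometry 7 km apart), GPS position error,
behaviour-dependent sampling, wind-dependent flight, or any feedback of
weather on trip timing beyond the departure model. Passing the recovery
tests therefore shows the pipeline's logic is correct under the stated
statistical structure, not that the thresholds are optimal for any real
logger data.

The field-survey generator emits the 10 × 5 × 3 × 2 = 300-row design
(10 transects, 5 fields each, 3 periods, morning/evening halves), with
vegetation height lognormal within periods and rising in median across
them, presence following a logistic model with height and period effects
plus nested random intercepts, and community counts coupled to the same
field-quality axis so wader and gull associations are recoverable.

## Numerical choices and degenerate inputs

* Distances use the haversine formula on a 6371.0088 km sphere; at ranges
  under 100 km the great-circle error against an ellipsoid is far below
  GPS noise, so no projection is used.
* Timestamps are UTC everywhere; only the sunrise computation reasons about
  local solar time, by construction of the nearest-sunrise rule.
* Zero-length trips, tracks that never leave the nest radius, empty
  scenarios and zero-variance weather all degrade to empty-but-valid
  outputs rather than errors; genuinely contradictory configuration
  (mixtures not summing to one, inverted IQRs, a 113.5 mm head+bill) errors
  with the offending field named.
* The problem sizes in the test suite — an S1 run of ~1040 trips, 1000
  permutation refits, 200-iteration bootstraps, 100-replicate recovery
  loops — were chosen so the whole suite completes in minutes while keeping
  every binomial check's error bars tight enough to be informative.

## Known limitations

* Random slopes, non-logit links, observation-level overdispersion and
  spatial autocorrelation are out of scope; the fitter is deliberately a
  random-intercept specialist.
* The two foraging speed thresholds and the trip filters are conventions
  exposed as configuration, not estimated quantities.
* Percentile bootstrap intervals for `r` undercover in small designs (see
  above).
* The nested-intercept path solves a dense system sized by the number of
  random levels; it is comfortable at survey scale (60 levels) but not
  built for thousands of levels.
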