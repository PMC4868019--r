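# gullforage

Habitat-choice analysis for central-place foraging seabirds tracked by GPS.

Breeding gulls commute between a colony and feeding areas, and omnivorous
species such as the lesser black-backed gull (*Larus fuscus*) split their
foraging between the sea and agricultural land. Given raw GPS fixes, a nest
location per bird, a land polygon mask and a colony weather series, this
package reconstructs each bird's foraging trips and asks what drives the
choice of land over sea: time of day relative to sunrise, weather, breeding
stage, sex — and how much is simply the individual.

The pipeline is:

1. **Trip segmentation** — a trip starts when a bird moves more than 500 m
   from its nest and ends on return; departure and return instants are the
   midpoints of the bracketing fix pairs (`segment_trips()`, `filter_trips()`).
2. **Foraging classification** — trip fixes are interpolated onto a regular
   300 s grid so each point represents equal time; a point is "likely
   foraging" iff its speed is in `[0, 4]` m/s and it lies at least 3 km from
   the colony; each foraging point is land or sea by a boundary-inclusive
   point-in-polygon test. The per-trip response is `p_land`, the proportion of
   foraging points on land; trips are classed land (`> 0.95`), mixed
   (`0.05–0.95`), sea (`< 0.05`) or unclassified (no foraging points)
   (`classify_trips()`).
3. **Covariates** — sunrise proximity `cos(pi * t / 12)` of signed hours
   since the nearest sunrise (NOAA solar calculation), 24 h pre-departure
   weather summaries (mean of the values at departure, −6, −12, −18 h; sum
   for precipitation), breeding-stage calendar windows, and sex from the
   113.5 mm head+bill discriminant (`annotate_trips()`).
4. **Modelling** — the counts `(n_land, n_forage_points)` are modelled by a
   binomial logistic mixed model with an individual random intercept, fitted
   by maximum likelihood with a Laplace approximation (`fit_glmm()`); the
   model toolkit covers AICc ranking, Nakagawa–Schielzeth marginal and
   conditional R², two-SD predictor standardization, the collinearity
   condition number, and single-term-deletion likelihood-ratio tests.
5. **Repeatability** — the between-individual share of latent-scale variance,
   `r = sigma^2_ind / (sigma^2_ind + pi^2/3)`, with a label-permutation
   p-value and a parametric-bootstrap confidence interval
   (`repeatability()`).
6. **Field surveys** — gull presence on agricultural fields as a Bernoulli
   GLMM with field-within-transect nested random intercepts
   (`fit_field_models()`).

A synthetic generator (`scenario()`, `simulate_world()`, `simulate_weather()`,
`simulate_tracks()`, `simulate_field_observations()`) produces GPS tracks,
weather and field surveys with known ground truth, so every stage is testable
without any tracking download. The standard scenario `scenario_s1()` encodes
the study conditions: 19 individuals over three seasons, ~1038 trips, a
21.5/9.1/69.4% land/mixed/sea classified-trip mixture, class-wise lognormal
durations and distances, and a between-individual propensity SD implying a
latent repeatability of 0.814.

## Worked example

```r
library(gullforage)

sc      <- scenario_s1(seed = 1)
world   <- simulate_world(sc)
weather <- simulate_weather(sc)
tracks  <- simulate_tracks(sc, world, weather)

seg   <- segment_trips(derive_speed(tracks$fixes), world$nests)
flt   <- filter_trips(seg$trips)
trips <- classify_trips(seg, world$colony, world$mask, trips = flt$trips)
table(trips$trip_class)
#>         land        mixed          sea unclassified
#>          218          101          706           15
median(trips$duration_h)
#> [1] 5.08
```

Of the 1040 filtered trips, 21.3% were pure land trips, 9.9% mixed and 68.9%
pure sea (of the 1025 classified), with a pooled median trip duration of
5.1 h. Fitting the trip-level model and computing repeatability:

```r
ann <- annotate_trips(trips, weather, world$individuals, world$colony)
dat <- ann[ann$n_forage_points > 0, ]
std <- standardize_predictors(dat, c("cloud", "temp", "ppt", "windEW", "windNS"))
fit <- fit_glmm(cbind(n_land, n_forage_points - n_land) ~
                  cloud + temp + sunrise_prox + (1 | individual_id),
                std$data)
summary(fit)
#> Fixed effects (logit scale):
#>  (Intercept)        cloud         temp sunrise_prox
#>      -3.3446       0.5930      -0.4727       1.1179
#> Random-effect SDs:
#> individual_id
#>        4.0621

repeatability(fit, n_perm = 200, n_boot = 200, seed = 42)
#> Repeatability r = 0.834 (p = 0.004975 by randomization, 200 iter)
#> 95% parametric-bootstrap CI: 0.714 - 0.894 (200 iter)
```

Terrestrial foraging rises with sunrise proximity and cloud cover and falls
with temperature (coefficients are on the logit scale, numeric predictors
scaled by two standard deviations so effects are comparable); the individual
random-intercept SD of 4.06 corresponds to a latent-scale repeatability of
0.83 — which individual a trip belongs to explains most of the latent
variance in land use, and the permutation p-value sits at its floor.

## Vignette

`vignettes/foraging-analysis.Rmd` documents the model, the generator's
design and its calibration to the study conditions, the numerical choices in
the Laplace fitter, and known limitations.
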