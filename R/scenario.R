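## Scenario configuration for the synthetic study generator. The standard
## scenario S1 encodes the study conditions: 19 individuals over three
## breeding seasons, ~1038 trips in the 20 May - 21 July focal window,
## a classified-trip class mixture of 21.5 / 9.1 / 69.4 % (land/mixed/sea)
## plus a 1.35% unclassified rate, class-wise lognormal durations and maximum
## distances matched to printed medians and interquartile ranges, and a
## between-individual propensity SD chosen so that the latent-scale
## repeatability sigma^2/(sigma^2 + pi^2/3) equals 0.814.

cfg_err <- function(field, why) {
  stop(sprintf("invalid scenario: field '%s' %s", field, why), call. = FALSE)
}

#' Build a synthetic-study scenario
#'
#' All generator knobs in one validated configuration object. Defaults are
#' the standard scenario S1 (see [scenario_s1()]).
#'
#' @param seed Integer root seed; every component derives its own stream.
#' @param n_individuals,n_years Study size.
#' @param first_year First calendar year of tracking.
#' @param colony `c(lon, lat)` of the colony (default: a small island 7 km
#'   west of a large mainland island at 57.28 N).
#' @param nest_jitter_m Nest scatter around the colony centre (metres).
#' @param sampling_interval GPS sampling interval in seconds (default 300).
#' @param gap_rate Per-fix probability of starting a short data gap.
#' @param long_gap_rate Per-trip probability of a ~2 h data gap.
#' @param trips_per_ind_year Poisson mean of trips per individual-year.
#' @param trip_class_mixture Named probabilities `c(land=, mixed=, sea=)` of
#'   the classified-trip classes; must sum to 1.
#' @param unclassified_rate Probability a trip yields zero foraging points.
#' @param duration_medians_h,duration_iqrs_h Per-class lognormal medians
#'   (named vector) and IQRs (2-row matrix or list `c(q25, q75)` per class).
#' @param maxdist_medians_km,maxdist_iqrs_km Same for maximum distances.
#' @param individual_propensity_sd SD of per-individual logit-scale
#'   land-propensity intercepts.
#' @param fixed_effects Coefficients `c(sunrise =, cloud =, temp =)` on the
#'   land-choice logit (cloud and temperature enter as z-scores of their 24 h
#'   summaries).
#' @param trip_noise_scale Scale of the logistic trip-level latent noise.
#' @param impurity_rate Probability that a pure land/sea trip contains one
#'   opposite-habitat foraging point (applied when the trip has >= 25
#'   foraging points).
#' @param depart_sunrise_frac Fraction of departures drawn from the pre-dawn
#'   peak (wrapped normal centred 1 h before sunrise, SD 2 h) rather than
#'   uniformly over the day.
#' @param season_window `c(start, end)` as `"mm-dd"` strings.
#' @param commute_speed_ms,forage_speed_ms Commuting speed and slow-foraging
#'   speed band (m/s).
#' @param weather Weather-series configuration: list with `rho` (6-hourly
#'   lag-1 autocorrelation), `temp_mean`, `temp_sd`, `cloud_mean`,
#'   `cloud_sd`, `wind_mean_ew`, `wind_mean_ns`, `wind_sd`, `precip_scale`.
#' @return A validated list of class `gf_scenario`.
#' @export
scenario <- function(seed = 1L,
                     n_individuals = 19L,
                     n_years = 3L,
                     first_year = 2011L,
                     colony = c(lon = 17.9667, lat = 57.2833),
                     nest_jitter_m = 50,
                     sampling_interval = 300,
                     gap_rate = 0.010,
                     long_gap_rate = 0.01,
                     trips_per_ind_year = 19.1,
                     trip_class_mixture = c(land = 220, mixed = 93, sea = 711) / 1024,
                     unclassified_rate = 14 / 1038,
                     duration_medians_h = c(land = 6.2, sea = 3.9, mixed = 11.3),
                     duration_iqrs_h = list(land = c(4.1, 9.8), sea = c(2.2, 6.8),
                                            mixed = c(8.1, 15.0)),
                     maxdist_medians_km = c(land = 20.8, sea = 23.2, mixed = 39.3),
                     maxdist_iqrs_km = list(land = c(17.4, 22.7), sea = c(13.2, 41.1),
                                            mixed = c(22.6, 49.3)),
                     individual_propensity_sd = sqrt(0.814 / 0.186 * pi^2 / 3),
                     fixed_effects = c(sunrise = 1.0, cloud = 0.4, temp = -0.4),
                     trip_noise_scale = 0.7,
                     impurity_rate = 0.12,
                     depart_sunrise_frac = 0.35,
                     season_window = c(start = "05-20", end = "07-21"),
                     commute_speed_ms = 10,
                     forage_speed_ms = c(0.2, 1.2),
                     weather = list(rho = 0.8, temp_mean = 12, temp_sd = 3,
                                    cloud_mean = 55, cloud_sd = 28,
                                    wind_mean_ew = 3, wind_mean_ns = 1,
                                    wind_sd = 3, precip_scale = 1.5)) {
  sc <- as.list(environment())
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) cfg_err("seed", "must be a single integer")
  if (n_individuals < 0) cfg_err("n_individuals", "must be >= 0")
  if (n_years < 1) cfg_err("n_years", "must be >= 1")
  if (length(colony) != 2 || abs(colony[2]) > 90) cfg_err("colony", "must be c(lon, lat)")
  if (any(trip_class_mixture < 0)) cfg_err("trip_class_mixture", "has negative entries")
  if (abs(sum(trip_class_mixture) - 1) > 1e-9) cfg_err("trip_class_mixture", "must sum to 1")
  if (!all(c("land", "mixed", "sea") %in% names(trip_class_mixture))) {
    cfg_err("trip_class_mixture", "needs named entries land, mixed, sea")
  }
  if (individual_propensity_sd < 0) cfg_err("individual_propensity_sd", "must be >= 0")
  if (unclassified_rate < 0 || unclassified_rate >= 1) cfg_err("unclassified_rate", "must be in [0, 1)")
  for (cls in c("land", "sea", "mixed")) {
    m <- duration_medians_h[[cls]]; q <- duration_iqrs_h[[cls]]
    if (!(m > 0) || any(q <= 0)) cfg_err("duration_medians_h", "must be strictly positive")
    if (!(q[1] < m && m < q[2])) cfg_err("duration_iqrs_h", sprintf("needs q25 < median < q75 for class %s", cls))
    m <- maxdist_medians_km[[cls]]; q <- maxdist_iqrs_km[[cls]]
    if (!(m > 0) || any(q <= 0)) cfg_err("maxdist_medians_km", "must be strictly positive")
    if (!(q[1] < m && m < q[2])) cfg_err("maxdist_iqrs_km", sprintf("needs q25 < median < q75 for class %s", cls))
  }
  if (sampling_interval <= 0) cfg_err("sampling_interval", "must be positive")
  if (gap_rate < 0 || gap_rate >= 1) cfg_err("gap_rate", "must be in [0, 1)")
  sc$seed <- as.integer(seed)
  sc$years <- seq(as.integer(first_year), length.out = as.integer(n_years))
  structure(sc, class = "gf_scenario")
}

#' The standard scenario S1
#'
#' Scenario defaults at a given seed.
#'
#' @param seed Root seed.
#' @return A `gf_scenario`.
#' @export
scenario_s1 <- function(seed = 1L) scenario(seed = seed)

#' @export
print.gf_scenario <- function(x, ...) {
  cat("<gf_scenario> ", x$n_individuals, " individuals x ", x$n_years,
      " years, ~", round(x$trips_per_ind_year * x$n_individuals * x$n_years),
      " trips, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Read / write a scenario as YAML
#'
#' @param path YAML file path.
#' @return `read_scenario()` returns a `gf_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y[setdiff(names(y), "years")]
  for (nm in c("colony", "trip_class_mixture", "duration_medians_h",
               "maxdist_medians_km", "fixed_effects", "season_window")) {
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  }
  do.call(scenario, y)
}

#' @rdname read_scenario
#' @param sc A `gf_scenario`.
#' @export
write_scenario <- function(sc, path) {
  out <- unclass(sc)
  out$years <- NULL
  ## named vectors must become YAML maps, and full double precision is kept
  ## so the mixture still sums to 1 within 1e-9 after a round trip
  out <- lapply(out, function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

## deterministic per-component child streams from one root seed
child_seed <- function(seed, stream) {
  offs <- c(world = 101L, weather = 211L, tracks = 307L, fields = 401L)
  as.integer((as.numeric(seed) * 48271 + offs[[stream]]) %% 2147483629)
}

## lognormal sdlog from a printed IQR: sigma = (ln q75 - ln q25) / (2 * 0.6745)
iqr_sdlog <- function(iqr) (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75))

## stratified normal sample with exact mean 0 and SD sd (one draw per
## probability stratum, then standardized); keeps a small-N study's
## between-individual spread at its nominal value for every seed
strat_normal <- function(n, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0 || n == 1L) return(rep(0, n))
  z <- stats::qnorm((seq_len(n) - stats::runif(n)) / n)
  z <- (z - mean(z)) / stats::sd(z) * sd
  sample(z)
}
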