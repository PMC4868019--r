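# one larger run shared by the convergence checks below (~5000 trips)
big_run <- local({
  sc <- scenario(seed = 31, n_individuals = 40L, n_years = 2L,
                 trips_per_ind_year = 65)
  world <- simulate_world(sc)
  list(sc = sc, world = world, tracks = simulate_tracks(sc, world))
})

test_that("all generators are deterministic for a fixed seed", {
  sc <- small_scenario(seed = 41)
  expect_identical(simulate_world(sc), simulate_world(sc))
  expect_identical(simulate_weather(sc), simulate_weather(sc))
  w <- simulate_world(sc)
  expect_identical(simulate_tracks(sc, w), simulate_tracks(sc, w))
  expect_identical(simulate_field_observations(sc), simulate_field_observations(sc))
})

test_that("an empty scenario yields an empty world and track set", {
  sc <- scenario(seed = 1, n_individuals = 0L)
  w <- simulate_world(sc)
  expect_equal(nrow(w$nests), 0L)
  tk <- simulate_tracks(sc, w)
  expect_equal(nrow(tk$fixes), 0L)
})

test_that("scenario validation names the offending field", {
  expect_error(scenario(trip_class_mixture = c(land = 0.5, mixed = 0.2, sea = 0.2)),
               "trip_class_mixture")
  expect_error(scenario(individual_propensity_sd = -1), "individual_propensity_sd")
  expect_error(scenario(duration_iqrs_h = list(land = c(7, 9.8), sea = c(2.2, 6.8),
                                               mixed = c(8.1, 15))),
               "duration_iqrs_h")
  expect_error(scenario(n_years = 0), "n_years")
})

test_that("every nest lies on the colony island within the configured jitter", {
  sc <- scenario_s1(seed = 42)
  w <- simulate_world(sc)
  d <- gf_haversine(w$nests$nest_lon, w$nests$nest_lat, sc$colony[1], sc$colony[2])
  expect_true(all(d <= sc$nest_jitter_m + 1e-6))
  expect_true(all(point_on_land(w$nests$nest_lon, w$nests$nest_lat, w$mask)))
  ## mainland west coast is ~7 km east of the colony: probe either side
  just_sea <- gf_destination(sc$colony[1], sc$colony[2], 90, 6800)
  just_land <- gf_destination(sc$colony[1], sc$colony[2], 90, 7200)
  expect_false(point_on_land(just_sea$lon, just_sea$lat, w$mask))
  expect_true(point_on_land(just_land$lon, just_land$lat, w$mask))
})

test_that("weather respects bounds, zero-variance degeneracy, and its autocorrelation", {
  sc <- scenario_s1(seed = 43)
  w <- simulate_weather(sc)
  expect_true(all(w$cloud >= 0 & w$cloud <= 100))
  expect_true(all(w$precip_rate >= 0))
  expect_true(all(diff(as.numeric(w$timestamp)) > 0))
  ## zero variance -> constant series
  sc0 <- scenario(seed = 1, weather = list(rho = 0.8, temp_mean = 10, temp_sd = 0,
                                           cloud_mean = 40, cloud_sd = 0,
                                           wind_mean_ew = 2, wind_mean_ns = 0,
                                           wind_sd = 0, precip_scale = 0))
  w0 <- simulate_weather(sc0)
  expect_equal(unique(w0$temp), 10)
  expect_equal(unique(w0$cloud), 40)
  expect_equal(unique(w0$precip_rate), 0)
  ## lag-1 autocorrelation of temperature near the configured value (n >= 400)
  scl <- scenario(seed = 44, n_years = 5L,
                  season_window = c(start = "04-30", end = "07-21"))
  wl <- simulate_weather(scl)
  expect_gte(nrow(wl), 400)
  ac <- by_year_ac <- stats::acf(wl$temp, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac - scl$weather$rho), 0.15)
})

test_that("a pure-land mixture yields only land ground-truth classes", {
  sc <- scenario(seed = 45, n_individuals = 4L, n_years = 1L,
                 trips_per_ind_year = 10,
                 trip_class_mixture = c(land = 1, mixed = 0, sea = 0),
                 unclassified_rate = 0)
  tk <- simulate_tracks(sc, simulate_world(sc))
  expect_true(all(tk$truth$class == "land"))
})

test_that("commute fixes are faster than foraging fixes within every trip", {
  tk <- simulate_tracks(small_scenario(46), simulate_world(small_scenario(46)))
  beh <- tk$fix_behavior$behavior
  sp <- tk$fixes$speed
  for (id in unique(tk$fix_behavior$truth_id)) {
    sel <- tk$fix_behavior$truth_id == id
    com <- sp[sel & beh == "commute"]
    fo <- sp[sel & startsWith(beh, "forage")]
    if (length(com) && length(fo)) expect_gt(min(com), max(fo))
  }
})

test_that("ground-truth class frequencies converge to the configured mixture", {
  tru <- big_run$tracks$truth
  cls <- tru$class[tru$class != "unclassified"]
  n <- length(cls)
  expect_gte(n, 4500)
  mix <- big_run$sc$trip_class_mixture
  for (k in c("land", "mixed", "sea")) {
    phat <- mean(cls == k)
    ci <- phat + c(-1, 1) * 3 * sqrt(mix[[k]] * (1 - mix[[k]]) / n)
    expect_true(mix[[k]] >= ci[1] && mix[[k]] <= ci[2])
  }
})

test_that("generated durations match their class lognormals (median and IQR within 10%)", {
  tru <- big_run$tracks$truth
  sc <- big_run$sc
  for (k in c("land", "sea", "mixed")) {
    d <- tru$duration_h[tru$class == k]
    expect_gte(length(d), 300)
    expect_lt(abs(stats::median(d) / sc$duration_medians_h[[k]] - 1), 0.10)
    q <- stats::quantile(d, c(0.25, 0.75))
    expect_lt(abs(q[[1]] / sc$duration_iqrs_h[[k]][1] - 1), 0.10)
    expect_lt(abs(q[[2]] / sc$duration_iqrs_h[[k]][2] - 1), 0.10)
  }
})

test_that("the individual intercepts carry the configured latent repeatability", {
  tru <- big_run$tracks$truth
  a <- tapply(tru$a_ind, tru$individual_id, mean)
  s2 <- stats::var(a)
  icc <- s2 / (s2 + pi^2 / 3)
  target <- big_run$sc$individual_propensity_sd^2 /
    (big_run$sc$individual_propensity_sd^2 + pi^2 / 3)
  expect_lt(abs(icc - target), 0.05)
})

test_that("zero propensity SD leaves no excess between-individual variation", {
  sc <- scenario(seed = 47, n_individuals = 10L, n_years = 1L,
                 trips_per_ind_year = 40, individual_propensity_sd = 0)
  tk <- simulate_tracks(sc, simulate_world(sc))
  tru <- tk$truth[tk$truth$class != "unclassified", ]
  land <- as.integer(tru$class == "land")
  ids <- tru$individual_id
  obs_var <- stats::var(tapply(land, ids, mean))
  ## permutation reference for the between-individual variance of land rates
  set.seed(1)
  perm <- replicate(400, stats::var(tapply(sample(land), ids, mean)))
  expect_gt(mean(perm >= obs_var), 0.01)
})

test_that("field observations have the survey design shape and plausible structure", {
  sc <- scenario_s1(seed = 48)
  obs <- simulate_field_observations(sc)
  expect_equal(nrow(obs), 300L)
  expect_equal(length(unique(obs$field_id)), 50L)
  expect_equal(length(unique(obs$transect_id)), 10L)
  ## each field belongs to exactly one transect
  expect_true(all(rowSums(table(obs$field_id, obs$transect_id) > 0) == 1))
  ## vegetation medians rise across periods
  med <- tapply(obs$veg_height, obs$obs_period, stats::median)
  expect_true(all(diff(med) > 0))
  expect_true(all(obs$veg_height > 0))
  expect_true(all(obs[c("lbbg", "lapwing", "oystercatcher", "earthworms")] >= 0))
})

test_that("a strong negative height slope depresses presence on tall fields", {
  obs <- simulate_field_observations(49, field_config(b_height = -2.5, b_period = c(0, 0),
                                                      sd_transect = 0, sd_field = 0))
  ter <- cut(obs$veg_height, stats::quantile(obs$veg_height, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("short", "mid", "tall"))
  rate <- tapply(obs$lbbg > 0, ter, mean)
  expect_gt(rate[["short"]], rate[["tall"]])
})

test_that("a null field model reproduces its intercept presence rate", {
  obs <- simulate_field_observations(50, field_config(b_height = 0, b_period = c(0, 0),
                                                      sd_transect = 0, sd_field = 0,
                                                      b0 = -0.4))
  phat <- mean(obs$lbbg > 0)
  p0 <- stats::plogis(-0.4)
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 300))
})
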