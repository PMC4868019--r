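## End-to-end orchestration: simulate (or load) -> segment -> classify ->
## annotate -> fit -> repeatability -> fields, with every stage's inputs and
## outputs persisted so stages can be re-run individually.

#' Run the full foraging analysis pipeline
#'
#' Orchestrates the whole analysis into a run directory. With a scenario in
#' the config the input data are generated; otherwise fixes, nests, mask and
#' weather are read from the configured paths. Products: `fixes.csv`,
#' `mask.geojson`, `weather.csv`, `trip_records.csv`, `annotated.csv`,
#' `exclusions.csv`, `fits.json`, `repeatability.json`, `field_ranking.json`,
#' `summary.json` and a `manifest.json` echoing the configuration and seeds.
#'
#' @param config A list (or YAML path) with entries: either `scenario` (a
#'   [scenario()] or arguments for one) or paths `fixes`, `nests`, `mask`,
#'   `weather`; optional `filter` ([filter_config()] arguments),
#'   `classify` (`v_low`, `v_high`, `min_dist_km`), `model` (fixed-effect
#'   RHS for the trip GLMM, default `"cloud + temp + sunrise_prox"`),
#'   `n_perm`, `n_boot` (default 0: skip the resampling inference),
#'   `fields` (logical, default `TRUE` when simulating).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the main in-memory products (`trips`,
#'   `annotated`, `fit`, `repeatability`, `field_ranking`, `summary`).
#' @export
run_all <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  simulated <- !is.null(config$scenario)
  if (simulated) {
    sc <- config$scenario
    if (!inherits(sc, "gf_scenario")) sc <- do.call(scenario, sc)
    world <- simulate_world(sc)
    weather <- simulate_weather(sc)
    tracks <- simulate_tracks(sc, world, weather)
    fixes <- tracks$fixes
    nests <- world$nests
    mask <- world$mask
    colony <- world$colony
    individuals <- world$individuals
    utils::write.csv(data.frame(individual_id = fixes$individual_id,
                                timestamp_utc = format_utc(fixes$timestamp),
                                lon = fixes$lon, lat = fixes$lat,
                                speed_ms = fixes$speed),
                     file.path(out_dir, "fixes.csv"), row.names = FALSE)
    write_mask(mask, file.path(out_dir, "mask.geojson"))
    write_weather(weather, file.path(out_dir, "weather.csv"))
    write_trip_records(tracks$truth, file.path(out_dir, "ground_truth.csv"))
  } else {
    for (what in c("fixes", "nests", "mask", "weather")) {
      if (is.null(config[[what]])) stop("config is missing '", what, "'", call. = FALSE)
      if (!file.exists(config[[what]])) stop("config '", what, "' path does not exist: ",
                                             config[[what]], call. = FALSE)
    }
    fixes <- read_fixes(config$fixes)
    nests <- utils::read.csv(config$nests, stringsAsFactors = FALSE)
    mask <- read_mask(config$mask)
    weather <- read_weather(config$weather)
    colony <- if (!is.null(config$colony)) unlist(config$colony) else
      c(mean(nests$nest_lon), mean(nests$nest_lat))
    individuals <- utils::read.csv(config$individuals, stringsAsFactors = FALSE)
  }
  fixes <- derive_speed(fixes)

  seg <- segment_trips(fixes, nests, radius = config$radius %||% 500)
  rules <- do.call(filter_config, config$filter %||% list())
  flt <- filter_trips(seg$trips, rules)
  utils::write.csv(flt$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)

  cl <- config$classify %||% list()
  trips <- classify_trips(seg, colony, mask, trips = flt$trips,
                          v_low = cl$v_low %||% 0, v_high = cl$v_high %||% 4,
                          min_dist_km = cl$min_dist_km %||% 3)
  write_trip_records(trips, file.path(out_dir, "trip_records.csv"))

  annotated <- annotate_trips(trips, weather, individuals, colony)
  write_trip_records(annotated, file.path(out_dir, "annotated.csv"))

  dat <- annotated[annotated$n_forage_points > 0, ]
  std <- standardize_predictors(dat, intersect(c("cloud", "temp", "ppt", "windEW", "windNS"),
                                               names(dat)))
  rhs <- config$model %||% "cloud + temp + sunrise_prox"
  fml <- stats::as.formula(paste(
    "cbind(n_land, n_forage_points - n_land) ~", rhs, "+ (1 | individual_id)"))
  fit <- fit_glmm(fml, std$data)
  write_fit_report(fit, file.path(out_dir, "fits.json"))

  n_perm <- config$n_perm %||% 0
  n_boot <- config$n_boot %||% 0
  rep_res <- NULL
  if (n_perm > 0 || n_boot > 0) {
    r <- repeatability_point(fit)
    p <- if (n_perm > 0) as.numeric(randomization_p(fit, n_perm, seed = config$seed %||% 1)) else NA
    ci <- if (n_boot > 0) bootstrap_ci(fit, n_boot, seed = (config$seed %||% 1) + 1) else c(NA, NA)
    rep_res <- list(r = r, p_randomization = p, ci_low = unname(ci[1]),
                    ci_high = unname(ci[2]), n_perm = n_perm, n_boot = n_boot)
  } else {
    rep_res <- list(r = repeatability_point(fit))
  }
  jsonlite::write_json(rep_res, file.path(out_dir, "repeatability.json"),
                       auto_unbox = TRUE, digits = NA)

  field_ranking <- NULL
  if (isTRUE(config$fields %||% simulated)) {
    obs <- if (simulated) simulate_field_observations(sc) else
      utils::read.csv(config$field_obs, stringsAsFactors = FALSE)
    ff <- fit_field_models(derive_presence(obs))
    field_ranking <- ff$ranking
    jsonlite::write_json(field_ranking, file.path(out_dir, "field_ranking.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  tab <- table(trips$trip_class)
  summary_list <- list(
    n_trips_segmented = nrow(seg$trips),
    n_trips_filtered = nrow(flt$trips),
    n_excluded = nrow(flt$exclusions),
    class_counts = as.list(tab),
    class_pct_of_classified = as.list(round(
      100 * tab[c("land", "mixed", "sea")] / sum(tab[c("land", "mixed", "sea")]), 2)),
    median_duration_h = stats::median(trips$duration_h),
    median_maxdist_km = stats::median(trips$max_distance_km),
    repeatability = rep_res$r)
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gullforage")),
    seed = if (simulated) sc$seed else config$seed %||% NA,
    config = if (simulated) "scenario (echoed in scenario.yaml)" else config,
    created = format_utc(Sys.time()))
  if (simulated) write_scenario(sc, file.path(out_dir, "scenario.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(trips = trips, annotated = annotated, fit = fit,
                 repeatability = rep_res, field_ranking = field_ranking,
                 summary = summary_list))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
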