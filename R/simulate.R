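## Synthetic world, weather and GPS-track generation with ground truth.
## Geometry: a small colony island with a large mainland island 7 km to its
## east; land foraging happens on the mainland, sea foraging in the open
## water west and south of the colony. Every trip is rendered as out-commute
## (fast fixes), foraging bout(s) (slow fixes on the class's habitat), and
## return commute, on a regular sampling grid with occasional gaps, and a
## sidecar table records the ground truth of every trip and fix.

## ---- world -----------------------------------------------------------------

## regular polygon ring around a centre (approximate metric circle)
ring_around <- function(lon, lat, radius_m, nvert = 16) {
  b <- seq(0, 360, length.out = nvert + 1)[-(nvert + 1)]
  p <- gf_destination(lon, lat, b, radius_m)
  as.matrix(p)
}

#' Generate the synthetic world: land mask, nests, individuals
#'
#' The mask has two polygons: a small colony island (600 m radius) and a
#' rectangular mainland whose west coast lies 7 km east of the colony,
#' extending 85 km east and 60 km north and south. Nests are scattered within
#' `nest_jitter_m` of the colony centre (all on the colony island).
#' Individuals receive head-plus-bill lengths drawn clear of the 113.5 mm
#' discriminant, fixing their sex.
#'
#' @param sc A [scenario()].
#' @return A list of class `gf_world`: `mask` (`gf_mask`), `colony`,
#'   `nests` (`individual_id`, `nest_lon`, `nest_lat`), `individuals`
#'   (`individual_id`, `head_bill`, `sex`).
#' @export
simulate_world <- function(sc) {
  stopifnot(inherits(sc, "gf_scenario"))
  set.seed(child_seed(sc$seed, "world"))
  colony <- sc$colony
  island <- ring_around(colony[1], colony[2], 600)
  west <- gf_destination(colony[1], colony[2], 90, 7000)   # mainland west coast
  ## rectangle in degrees around the west-coast anchor
  dlat <- 60000 / 111194.9
  dlon_east <- 85000 / (111194.9 * cos(colony[2] * pi / 180))
  mainland <- rbind(
    c(west$lon, west$lat - dlat),
    c(west$lon + dlon_east, west$lat - dlat),
    c(west$lon + dlon_east, west$lat + dlat),
    c(west$lon, west$lat + dlat))
  mask <- gf_mask(list(island, mainland), names = c("colony island", "mainland"))

  n <- sc$n_individuals
  if (n > 0) {
    ids <- sprintf("bird%02d", seq_len(n))
    b <- stats::runif(n, 0, 360)
    d <- sqrt(stats::runif(n)) * sc$nest_jitter_m
    nest <- gf_destination(colony[1], colony[2], b, d)
    sex_is_male <- stats::runif(n) < 0.5
    hb <- ifelse(sex_is_male, stats::rnorm(n, 119, 2.2), stats::rnorm(n, 108, 2.2))
    hb <- pmin(pmax(hb, 100), 130)
    hb[abs(hb - 113.5) < 0.2] <- 113.5 + sign(hb[abs(hb - 113.5) < 0.2] - 113.5 + 0.01) * 0.3
    nests <- data.frame(individual_id = ids, nest_lon = nest$lon, nest_lat = nest$lat)
    individuals <- data.frame(individual_id = ids, head_bill = round(hb, 1),
                              sex = sex_from_morphometrics(round(hb, 1)))
  } else {
    nests <- data.frame(individual_id = character(), nest_lon = numeric(),
                        nest_lat = numeric())
    individuals <- data.frame(individual_id = character(), head_bill = numeric(),
                              sex = factor(character(), levels = c("female", "male")))
  }
  structure(list(mask = mask, colony = colony, nests = nests,
                 individuals = individuals), class = "gf_world")
}

#' @export
print.gf_world <- function(x, ...) {
  cat("<gf_world> ", nrow(x$nests), " nests, ", length(x$mask$polygons),
      " land polygon(s)\n", sep = "")
  invisible(x)
}

## ---- weather ---------------------------------------------------------------

ar1 <- function(n, mean, sd, rho) {
  if (sd == 0 || n == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  for (t in seq_len(n)[-1]) x[t] <- rho * x[t - 1] + innov[t]
  mean + x
}

#' Generate a 6-hourly colony weather series
#'
#' First-order autocorrelated series for cloud cover (clamped to 0-100%),
#' 2 m air temperature, precipitation rate (non-negative), and east/north
#' 10 m wind components, covering each season window (plus a 2-day lead so
#' that 24 h pre-departure summaries are always available).
#'
#' @param sc A [scenario()].
#' @return A `gf_weather` data frame.
#' @export
simulate_weather <- function(sc) {
  stopifnot(inherits(sc, "gf_scenario"))
  set.seed(child_seed(sc$seed, "weather"))
  w <- sc$weather
  blocks <- lapply(sc$years, function(yr) {
    t0 <- as.POSIXct(sprintf("%d-%s 00:00:00", yr, sc$season_window[["start"]]), tz = "UTC") - 2 * 86400
    t1 <- as.POSIXct(sprintf("%d-%s 23:59:59", yr, sc$season_window[["end"]]), tz = "UTC") + 86400
    ts <- seq(t0, t1, by = 6 * 3600)
    n <- length(ts)
    cloud <- pmin(pmax(ar1(n, w$cloud_mean, w$cloud_sd, w$rho), 0), 100)
    temp <- ar1(n, w$temp_mean, w$temp_sd, w$rho)
    pr <- pmax(ar1(n, 0, 1, w$rho) - 0.3, 0) * w$precip_scale
    data.frame(timestamp = ts, cloud = cloud, temp = temp, precip_rate = pr,
               wind_ew = ar1(n, w$wind_mean_ew, w$wind_sd, w$rho),
               wind_ns = ar1(n, w$wind_mean_ns, w$wind_sd, w$rho))
  })
  validate_weather(do.call(rbind, blocks))
}

## ---- tracks ----------------------------------------------------------------

## One trip's fixes: commute/forage waypoints sampled on the grid.
## Returns vectors, not data frames, to keep the 1000-trip loop cheap.
## bout_s: absolute dwell seconds per site (NA = proportional share of the
## remaining foraging time per forage_split); used for short impurity bouts.
render_trip <- function(dep, D_h, sites, forage_split, nest, colony, sc,
                        v = sc$commute_speed_ms, bout_s = NULL) {
  step <- sc$sampling_interval
  ## legs: nest -> site1 [-> site2] -> nest
  way <- rbind(c(nest[1], nest[2]), do.call(rbind, sites), c(nest[1], nest[2]))
  nlegs <- nrow(way) - 1L
  leg_d <- gf_haversine(way[-nrow(way), 1], way[-nrow(way), 2],
                        way[-1, 1], way[-1, 2])
  t_commute <- sum(leg_d) / v
  F_tot <- max(D_h * 3600 - t_commute, 0.08 * D_h * 3600)
  if (is.null(bout_s)) {
    dwell <- forage_split * F_tot          # one dwell per site
  } else {
    fixed <- !is.na(bout_s)
    rem <- max(F_tot - sum(bout_s[fixed]), 120)
    dwell <- bout_s
    dwell[!fixed] <- forage_split[!fixed] / sum(forage_split[!fixed]) * rem
  }
  ## piecewise schedule of (time, lon, lat, mode)
  times <- dep
  mode <- character(0)
  pts <- matrix(way[1, ], 1)
  tcur <- dep
  for (l in seq_len(nlegs)) {
    tcur <- tcur + leg_d[l] / v
    pts <- rbind(pts, way[l + 1L, ])
    times <- c(times, tcur)
    mode <- c(mode, "commute")
    if (l < nlegs) {                        # dwell at site l
      tcur <- tcur + dwell[l]
      pts <- rbind(pts, way[l + 1L, ])
      times <- c(times, tcur)
      mode <- c(mode, "forage")
    }
  }
  ret <- tcur
  grid <- seq(dep + step, ret - step / 2, by = step)
  if (!length(grid)) return(NULL)
  seg <- findInterval(grid, times, rightmost.closed = TRUE)
  seg[seg < 1] <- 1; seg[seg > length(mode)] <- length(mode)
  frac <- (grid - times[seg]) / pmax(times[seg + 1L] - times[seg], 1)
  lon <- pts[seg, 1] + frac * (pts[seg + 1L, 1] - pts[seg, 1])
  lat <- pts[seg, 2] + frac * (pts[seg + 1L, 2] - pts[seg, 2])
  m <- mode[seg]
  nfx <- length(grid)
  ## foraging jitter: slow random walk around the site
  fo <- which(m == "forage")
  if (length(fo)) {
    stepm <- 70
    jlon <- stats::rnorm(nfx, 0, stepm) / (111194.9 * cos(colony[2] * pi / 180))
    jlat <- stats::rnorm(nfx, 0, stepm) / 111194.9
    for (sid in unique(seg[fo])) {
      ii <- fo[seg[fo] == sid]
      lon[ii] <- lon[ii] + pmin(pmax(cumsum(jlon[ii]), -0.009), 0.009)
      lat[ii] <- lat[ii] + pmin(pmax(cumsum(jlat[ii]), -0.006), 0.006)
    }
  }
  speed <- ifelse(m == "commute", v + stats::rnorm(nfx, 0, 0.3),
                  stats::runif(nfx, sc$forage_speed_ms[1], sc$forage_speed_ms[2]))
  ## behaviour labels carry the habitat of the dwell site
  behav <- m
  if (length(fo)) {
    site_idx <- pmax(1L, (seg[fo] ) %/% 2L)   # dwell segments are 2,4,...
    behav[fo] <- paste0("forage_", names(sites)[site_idx])
  }
  ## data gaps
  keep <- rep(TRUE, nfx)
  gs <- which(stats::runif(nfx) < sc$gap_rate)
  for (g in gs) keep[seq(g, min(nfx, g + stats::rgeom(1, 0.4)))] <- FALSE
  if (stats::runif(1) < sc$long_gap_rate && nfx > 10) {
    g0 <- sample(2:(nfx - 8), 1)
    keep[seq(g0, min(nfx - 1, g0 + ceiling(7200 / step)))] <- FALSE
  }
  keep[c(1L, nfx)] <- TRUE
  list(time = grid[keep], lon = lon[keep], lat = lat[keep],
       speed = pmax(speed[keep], 0.05), behav = behav[keep], ret = ret)
}

#' Generate GPS tracks with ground truth
#'
#' Draws per-individual logit-scale land-propensity intercepts (stratified
#' normal with the configured SD), schedules trips over each season with
#' departures mixing a pre-dawn peak and a uniform component, computes each
#' trip's latent land propensity from the individual intercept, the
#' sunrise-proximity and 24 h weather covariates and logistic trip noise,
#' and converts propensities to land/mixed/sea classes by empirical-quantile
#' thresholds so the realized classified-trip mixture matches the configured
#' one. Durations and maximum distances are drawn from the class-wise
#' lognormals; each trip is rendered as commute + foraging fixes with gaps,
#' and bracketed by at-nest fixes.
#'
#' @param sc A [scenario()].
#' @param world A [simulate_world()] result.
#' @param weather A [simulate_weather()] series (generated if omitted).
#' @return List of class `gf_tracks`: `fixes` (public fix table), `truth`
#'   (per-trip ground truth: class, land fraction, latent propensity,
#'   individual intercept, departure/return, duration, distance),
#'   `fix_behavior` (per-fix ground-truth labels), `individuals`.
#' @export
simulate_tracks <- function(sc, world, weather = NULL) {
  stopifnot(inherits(sc, "gf_scenario"), inherits(world, "gf_world"))
  if (is.null(weather)) weather <- simulate_weather(sc)
  set.seed(child_seed(sc$seed, "tracks"))
  N <- sc$n_individuals
  empty <- list(fixes = data.frame(individual_id = character(),
                                   timestamp = as.POSIXct(character(), tz = "UTC"),
                                   lon = numeric(), lat = numeric(), speed = numeric()),
                truth = data.frame(), fix_behavior = data.frame(),
                individuals = world$individuals)
  if (N == 0L) return(structure(empty, class = "gf_tracks"))
  colony <- sc$colony
  a <- strat_normal(N, sc$individual_propensity_sd)
  ids <- world$nests$individual_id

  ## ---- trip skeleton -------------------------------------------------------
  rows <- list()
  for (yi in seq_along(sc$years)) {
    yr <- sc$years[yi]
    t0 <- as.POSIXct(sprintf("%d-%s 12:00:00", yr, sc$season_window[["start"]]), tz = "UTC")
    t1 <- as.POSIXct(sprintf("%d-%s 12:00:00", yr, sc$season_window[["end"]]), tz = "UTC")
    ndays <- as.numeric(difftime(t1, t0, units = "days"))
    for (i in seq_len(N)) {
      nt <- stats::rpois(1, sc$trips_per_ind_year)
      if (nt == 0) next
      day <- sort(stats::runif(nt, 0, ndays - 1))
      date <- as.Date(t0, tz = "UTC") + floor(day)
      sr <- sunrise_time(colony[1], colony[2], date)
      pre <- stats::runif(nt) < sc$depart_sunrise_frac
      tsr <- ifelse(pre, stats::rnorm(nt, -1, 2), stats::runif(nt, -10, 12))
      dep <- as.numeric(sr) + tsr * 3600
      rows[[length(rows) + 1L]] <- data.frame(ind = i, year = yr, dep = dep)
    }
  }
  tr <- do.call(rbind, rows)
  tr <- tr[order(tr$ind, tr$dep), ]
  n_tr <- nrow(tr)

  ## covariates at departure
  dep_ct <- as.POSIXct(tr$dep, origin = "1970-01-01", tz = "UTC")
  tsr_h <- hours_since_sunrise(dep_ct, colony[1], colony[2])
  sprox <- sunrise_proximity(tsr_h)
  ws <- weather_summary(weather, dep_ct)
  zc <- (ws$cloud - sc$weather$cloud_mean) / max(sc$weather$cloud_sd, 1e-6)
  zt <- (ws$temp - sc$weather$temp_mean) / max(sc$weather$temp_sd, 1e-6)
  fe <- sc$fixed_effects
  eta <- a[tr$ind] + fe[["sunrise"]] * sprox + fe[["cloud"]] * zc +
    fe[["temp"]] * zt + sc$trip_noise_scale * stats::rlogis(n_tr)

  uncl <- stats::runif(n_tr) < sc$unclassified_rate
  mix <- sc$trip_class_mixture
  qs <- stats::quantile(eta[!uncl], c(mix[["sea"]], mix[["sea"]] + mix[["mixed"]]))
  cls <- ifelse(uncl, "unclassified",
                ifelse(eta < qs[1], "sea", ifelse(eta < qs[2], "mixed", "land")))

  med_d <- sc$duration_medians_h; med_x <- sc$maxdist_medians_km
  D <- numeric(n_tr); dmax <- numeric(n_tr)
  for (k in c("land", "sea", "mixed")) {
    ii <- cls == k
    D[ii] <- stats::rlnorm(sum(ii), log(med_d[[k]]), iqr_sdlog(sc$duration_iqrs_h[[k]]))
    dmax[ii] <- stats::rlnorm(sum(ii), log(med_x[[k]]), iqr_sdlog(sc$maxdist_iqrs_km[[k]]))
  }
  ii <- cls == "unclassified"
  D[ii] <- stats::rlnorm(sum(ii), log(med_d[["sea"]]), 0.7)
  dmax[ii] <- stats::rlnorm(sum(ii), log(12), 0.4)
  ## per-trip commute speed; feasibility: commute must fit inside the trip
  v_trip <- sc$commute_speed_ms * stats::runif(n_tr, 0.92, 1.08)
  v_trip[cls == "unclassified"] <- sc$commute_speed_ms
  cap <- ifelse(cls == "mixed", 0.28, 0.45) * D * v_trip * 3.6
  dmax <- pmin(dmax, pmax(cap, 4.5))
  dmax <- pmax(dmax, ifelse(cls %in% c("land", "mixed"), 9.5, 4.5))

  ## within-trip land fraction of foraging time
  f <- ifelse(cls == "land", 1, 0)
  mi <- cls == "mixed"
  f[mi] <- 0.1 + 0.8 * stats::plogis((eta[mi] - mean(qs)) / 2)
  ## impurity: a short opposite-habitat bout, only on trips with enough
  ## foraging time that its one or two points stay below the 5% class bound
  F_est <- D * 3600 - 2 * dmax * 1000 / v_trip
  impure <- stats::runif(n_tr) < sc$impurity_rate & cls %in% c("land", "sea") &
    F_est >= 13500

  ## resolve overlaps: push a departure to after the previous return
  ret <- tr$dep + D * 3600
  for (j in seq_len(n_tr)[-1]) {
    if (tr$ind[j] == tr$ind[j - 1] && tr$dep[j] < ret[j - 1] + 1800) {
      tr$dep[j] <- ret[j - 1] + 1800 + stats::runif(1, 0, 1800)
      ret[j] <- tr$dep[j] + D[j] * 3600
    }
  }
  ## drop trips pushed outside the season (covariates for shifted trips are
  ## recomputed at annotation time from the actual departure)
  season_end <- as.numeric(as.POSIXct(sprintf("%d-%s 23:00:00", tr$year,
                                              sc$season_window[["end"]]), tz = "UTC"))
  ok <- ret <= season_end
  tr <- tr[ok, ]; D <- D[ok]; dmax <- dmax[ok]; cls <- cls[ok]; f <- f[ok]
  impure <- impure[ok]; eta <- eta[ok]; ret <- ret[ok]; sprox <- sprox[ok]
  ws <- ws[ok, ]; n_tr <- nrow(tr)

  ## ---- rendering -----------------------------------------------------------
  acc <- list(id = list(), t = list(), lon = list(), lat = list(),
              sp = list(), beh = list(), key = list())
  truth <- vector("list", n_tr)
  for (j in seq_len(n_tr)) {
    i <- tr$ind[j]
    nest <- c(world$nests$nest_lon[i], world$nests$nest_lat[i])
    sites <- list(); split <- numeric(0); bout <- NULL
    if (cls[j] == "unclassified") {
      ## continuous commuting triangle over open water: no dwell, all bends
      ## well under 90 degrees, so no interpolated fix is ever slow
      d <- D[j] * 3600 * v_trip[j] / 2.77
      b1 <- stats::runif(1, 215, 275)
      A <- gf_destination(colony[1], colony[2], b1, d)
      B <- gf_destination(colony[1], colony[2], b1 + 45, d)
      sites <- list(sea = c(A$lon, A$lat), sea2 = c(B$lon, B$lat))
      split <- c(0.5, 0.5); bout <- c(0, 0)
      dmax[j] <- d / 1000
    } else if (cls[j] == "land") {
      s <- gf_destination(colony[1], colony[2], stats::runif(1, 78, 102), dmax[j] * 1000)
      sites <- list(land = c(s$lon, s$lat)); split <- 1
      if (impure[j]) {
        p <- gf_destination(colony[1], colony[2], 260, 4600)
        sites <- c(list(sea = c(p$lon, p$lat)), sites)
        split <- c(0, 1); bout <- c(650, NA)
      }
    } else if (cls[j] == "sea") {
      s <- gf_destination(colony[1], colony[2], stats::runif(1, 215, 300), dmax[j] * 1000)
      sites <- list(sea = c(s$lon, s$lat)); split <- 1
      if (impure[j]) {
        p <- gf_destination(colony[1], colony[2], 90, 9800)
        sites <- c(list(land = c(p$lon, p$lat)), sites)
        split <- c(0, 1); bout <- c(650, NA)
      }
    } else {
      ssea <- gf_destination(colony[1], colony[2], stats::runif(1, 215, 300), dmax[j] * 1000)
      dl <- min(max(9.5, 0.4 * dmax[j]), 16)
      sland <- gf_destination(colony[1], colony[2], stats::runif(1, 78, 102), dl * 1000)
      if (stats::runif(1) < 0.5) {
        sites <- list(sea = c(ssea$lon, ssea$lat), land = c(sland$lon, sland$lat))
        split <- c(1 - f[j], f[j])
      } else {
        sites <- list(land = c(sland$lon, sland$lat), sea = c(ssea$lon, ssea$lat))
        split <- c(f[j], 1 - f[j])
      }
    }
    rt <- render_trip(tr$dep[j], D[j], sites, split, nest, colony, sc,
                      v = v_trip[j], bout_s = bout)
    if (is.null(rt)) next
    ## bracketing at-nest fixes
    njit <- function(n) stats::rnorm(n, 0, 8) / 111194.9
    pre_t <- tr$dep[j] - c(2, 1) * sc$sampling_interval
    post_t <- rt$ret + c(1, 2) * sc$sampling_interval
    key <- sprintf("%s_y%d_%04d", ids[i], tr$year[j], j)
    acc$id[[j]] <- rep(ids[i], length(rt$t) + 4L)
    acc$t[[j]] <- c(pre_t, rt$t, post_t)
    acc$lon[[j]] <- c(nest[1] + njit(2), rt$lon, nest[1] + njit(2))
    acc$lat[[j]] <- c(nest[2] + njit(2), rt$lat, nest[2] + njit(2))
    acc$sp[[j]] <- c(stats::runif(2, 0, 0.3), rt$sp, stats::runif(2, 0, 0.3))
    acc$beh[[j]] <- c("nest", "nest", rt$beh, "nest", "nest")
    acc$key[[j]] <- rep(key, length(rt$t) + 4L)
    truth[[j]] <- data.frame(
      truth_id = key, individual_id = ids[i], year = tr$year[j],
      departure = as.POSIXct(tr$dep[j], origin = "1970-01-01", tz = "UTC"),
      return_time = as.POSIXct(rt$ret, origin = "1970-01-01", tz = "UTC"),
      duration_h = (rt$ret - tr$dep[j]) / 3600, maxdist_km = dmax[j],
      class = cls[j], f_land = f[j], eta = eta[j], a_ind = a[i],
      impure = impure[j], sunrise_prox = sprox[j],
      cloud24 = ws$cloud[j], temp24 = ws$temp[j])
  }
  fixes <- data.frame(
    individual_id = unlist(acc$id),
    timestamp = as.POSIXct(unlist(acc$t), origin = "1970-01-01", tz = "UTC"),
    lon = unlist(acc$lon), lat = unlist(acc$lat),
    speed = round(unlist(acc$sp), 2))
  o <- order(fixes$individual_id, fixes$timestamp)
  fix_behavior <- data.frame(truth_id = unlist(acc$key), behavior = unlist(acc$beh))[o, ]
  fixes <- fixes[o, ]
  dup <- duplicated(fixes[c("individual_id", "timestamp")])
  fixes <- fixes[!dup, ]; fix_behavior <- fix_behavior[!dup, ]
  rownames(fixes) <- rownames(fix_behavior) <- NULL
  structure(list(fixes = fixes, truth = do.call(rbind, truth),
                 fix_behavior = fix_behavior, individuals = world$individuals),
            class = "gf_tracks")
}

#' @export
print.gf_tracks <- function(x, ...) {
  cat("<gf_tracks> ", nrow(x$fixes), " fixes, ", nrow(x$truth), " trips, ",
      length(unique(x$fixes$individual_id)), " individuals\n", sep = "")
  invisible(x)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: world, weather, tracks and field observations from
#' one scenario.
#'
#' @param sc A [scenario()].
#' @return List with `scenario`, `world`, `weather`, `tracks`, `fields`.
#' @export
simulate_gps_study <- function(sc) {
  world <- simulate_world(sc)
  weather <- simulate_weather(sc)
  tracks <- simulate_tracks(sc, world, weather)
  fields <- simulate_field_observations(sc)
  list(scenario = sc, world = world, weather = weather, tracks = tracks,
       fields = fields)
}
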