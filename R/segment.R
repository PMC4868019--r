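## Trip segmentation: cut each individual's track into foraging trips with the
## 500 m nest-radius rule, interpolate trips onto a regular time grid, and
## filter to analyzable trips.

#' Segment tracks into foraging trips
#'
#' A trip opens at the first fix farther than `radius` from the nest that
#' follows a fix within the radius, and closes symmetrically at return. The
#' departure (return) instant is the midpoint of the bracketing inside/outside
#' fix pair, which is unbiased under regular sampling. Fixes inside the radius
#' belong to no trip. A trip still open when the track ends is kept but marked
#' `complete = FALSE`; a track that never leaves the radius yields no trips.
#'
#' @param fixes Fix table (columns `individual_id`, `timestamp`, `lon`, `lat`,
#'   optionally `speed`), time-sorted within individual.
#' @param nests Data frame with columns `individual_id`, `nest_lon`,
#'   `nest_lat` (one row per individual).
#' @param radius Nest radius in metres (default 500).
#' @return A list with `trips` (one row per trip: `trip_id`, `individual_id`,
#'   `departure`, `return_time`, `duration_h`, `max_distance_km`, `year`,
#'   `n_fixes`, `max_gap_min`, `complete`) and `fixes` (the input with a
#'   `trip_id` column, `NA` for at-nest fixes, and `dist_nest_m`).
#' @export
segment_trips <- function(fixes, nests, radius = 500) {
  stopifnot(all(c("individual_id", "timestamp", "lon", "lat") %in% names(fixes)),
            all(c("individual_id", "nest_lon", "nest_lat") %in% names(nests)))
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  idx <- match(fixes$individual_id, nests$individual_id)
  if (anyNA(idx)) {
    stop("no nest coordinates for individual(s): ",
         paste(unique(fixes$individual_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  fixes$dist_nest_m <- gf_haversine(fixes$lon, fixes$lat,
                                    nests$nest_lon[idx], nests$nest_lat[idx])
  fixes$trip_id <- NA_character_

  trips <- list()
  for (id in unique(fixes$individual_id)) {
    sel <- which(fixes$individual_id == id)
    out <- fixes$dist_nest_m[sel] > radius
    tt <- as.numeric(fixes$timestamp[sel])
    r <- rle(out)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    kt <- 0L
    for (k in which(r$values)) {
      a <- starts[k]; b <- ends[k]          # outside run [a, b] (local idx)
      kt <- kt + 1L
      trip_id <- sprintf("%s_t%03d", id, kt)
      dep <- if (a > 1L) (tt[a - 1L] + tt[a]) / 2 else tt[a]
      started <- a > 1L
      ret <- if (b < length(sel)) (tt[b] + tt[b + 1L]) / 2 else tt[b]
      complete <- started && b < length(sel)
      gaps <- if (b > a) diff(tt[a:b]) else numeric(0)
      rows <- sel[a:b]
      fixes$trip_id[rows] <- trip_id
      trips[[length(trips) + 1L]] <- data.frame(
        trip_id = trip_id, individual_id = id,
        departure = dep, return_time = ret,
        duration_h = (ret - dep) / 3600,
        max_distance_km = max(fixes$dist_nest_m[rows]) / 1000,
        year = as.integer(format(as.POSIXct(dep, origin = "1970-01-01", tz = "UTC"), "%Y")),
        n_fixes = length(rows),
        max_gap_min = if (length(gaps)) max(gaps) / 60 else 0,
        complete = complete)
    }
  }
  trips <- if (length(trips)) do.call(rbind, trips) else data.frame(
    trip_id = character(), individual_id = character(), departure = numeric(),
    return_time = numeric(), duration_h = numeric(), max_distance_km = numeric(),
    year = integer(), n_fixes = integer(), max_gap_min = numeric(), complete = logical())
  trips$departure <- as.POSIXct(trips$departure, origin = "1970-01-01", tz = "UTC")
  trips$return_time <- as.POSIXct(trips$return_time, origin = "1970-01-01", tz = "UTC")
  rownames(trips) <- NULL
  list(trips = trips, fixes = fixes)
}

#' Interpolate trip fixes onto a regular time grid
#'
#' Positions are linearly interpolated in time onto a `step`-second grid
#' between each trip's first and last fix. Grid points that fall inside a raw
#' data gap longer than `max_gap_min` are dropped rather than bridged. Speeds
#' on the grid are recomputed from consecutive grid positions. With every
#' point representing an equal slice of time, per-point summaries read as
#' time-proportion summaries.
#'
#' @param seg Output of [segment_trips()], or a fix table carrying `trip_id`.
#' @param step Grid step in seconds (default 300).
#' @param max_gap_min Maximum raw gap to interpolate across, minutes
#'   (default 45).
#' @return A data frame of interpolated trip fixes: `trip_id`,
#'   `individual_id`, `timestamp`, `lon`, `lat`, `speed`, `interpolated`.
#' @export
interpolate_trips <- function(seg, step = 300, max_gap_min = 45) {
  fixes <- if (is.list(seg) && !is.data.frame(seg)) seg$fixes else seg
  fixes <- fixes[!is.na(fixes$trip_id), , drop = FALSE]
  if (!nrow(fixes)) {
    return(data.frame(trip_id = character(), individual_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      lon = numeric(), lat = numeric(), speed = numeric(),
                      interpolated = logical()))
  }
  out <- lapply(split(fixes, fixes$trip_id), function(f) {
    f <- f[order(f$timestamp), ]
    if (nrow(f) < 2L) return(NULL)
    tt <- as.numeric(f$timestamp)
    grid <- seq(tt[1], tt[length(tt)], by = step)
    lon <- stats::approx(tt, f$lon, xout = grid)$y
    lat <- stats::approx(tt, f$lat, xout = grid)$y
    ## drop grid points strictly inside an over-long raw gap
    gaps <- which(diff(tt) > max_gap_min * 60)
    keep <- rep(TRUE, length(grid))
    for (g in gaps) keep[grid > tt[g] & grid < tt[g + 1L]] <- FALSE
    grid <- grid[keep]; lon <- lon[keep]; lat <- lat[keep]
    if (length(grid) < 2L) return(NULL)
    sp <- c(0, gf_haversine(lon[-length(lon)], lat[-length(lat)], lon[-1], lat[-1]) /
              diff(grid))
    data.frame(trip_id = f$trip_id[1], individual_id = f$individual_id[1],
               timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
               lon = lon, lat = lat, speed = sp,
               interpolated = !(grid %in% tt))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Trip filter configuration
#'
#' Thresholds for retaining analyzable foraging trips. Defaults: at least
#' 30 min duration, 3 km maximum distance, 5 raw fixes, largest internal gap
#' at most half the trip duration, completed trips only, departure date
#' between 20 May and 21 July (extendable to 30 April to include pre-laying).
#'
#' @param min_duration_h,min_distance_km,min_fixes,max_gap_frac,require_complete
#'   Filter thresholds.
#' @param window_start,window_end Analysis window as `"mm-dd"` strings,
#'   applied per calendar year.
#' @return A list of class `gf_filter_config`.
#' @export
filter_config <- function(min_duration_h = 0.5, min_distance_km = 3,
                          min_fixes = 5, max_gap_frac = 0.5,
                          require_complete = TRUE,
                          window_start = "05-20", window_end = "07-21") {
  structure(list(min_duration_h = min_duration_h, min_distance_km = min_distance_km,
                 min_fixes = min_fixes, max_gap_frac = max_gap_frac,
                 require_complete = require_complete,
                 window_start = window_start, window_end = window_end),
            class = "gf_filter_config")
}

#' Filter trips to analyzable foraging trips
#'
#' Applies [filter_config()] rules and logs every exclusion with the first
#' rule it failed. Input count always equals retained plus excluded.
#'
#' @param trips Trip table from [segment_trips()].
#' @param rules A [filter_config()].
#' @return A list with `trips` (retained) and `exclusions` (data frame
#'   `trip_id`, `reason`).
#' @export
filter_trips <- function(trips, rules = filter_config()) {
  stopifnot(inherits(rules, "gf_filter_config"))
  mmdd <- format(trips$departure, "%m-%d")
  reason <- rep(NA_character_, nrow(trips))
  chk <- function(bad, why) reason[is.na(reason) & bad] <<- why
  chk(rules$require_complete & !trips$complete, "incomplete")
  chk(trips$duration_h < rules$min_duration_h, "min_duration")
  chk(trips$max_distance_km < rules$min_distance_km, "min_distance")
  chk(trips$n_fixes < rules$min_fixes, "min_fixes")
  chk(trips$max_gap_min / 60 > rules$max_gap_frac * trips$duration_h, "max_gap")
  chk(mmdd < rules$window_start | mmdd > rules$window_end, "outside_window")
  keep <- is.na(reason)
  list(trips = trips[keep, , drop = FALSE],
       exclusions = data.frame(trip_id = trips$trip_id[!keep],
                               reason = reason[!keep]))
}
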