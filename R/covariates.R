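## Trip-record covariates: sunrise proximity, 24 h weather summaries,
## breeding stage, sex from morphometrics, and the annotation step that
## assembles the analysis table.

#' Summarize colony weather over the 24 h before a departure
#'
#' Each variable is linearly interpolated in time to the four instants
#' `t_dep, t_dep - 6 h, t_dep - 12 h, t_dep - 18 h`; the summary is the mean
#' of the four values, except precipitation rate where the sum is taken
#' (cumulative rainfall proxy for the preceding 24 h).
#'
#' @param weather A `gf_weather` series covering `[t_dep - 18 h, t_dep]`.
#' @param t_dep Departure instant(s), `POSIXct`.
#' @return Data frame with one row per departure: `cloud`, `temp`, `ppt`,
#'   `windEW`, `windNS`.
#' @export
weather_summary <- function(weather, t_dep) {
  tt <- as.numeric(weather$timestamp)
  td <- as.numeric(t_dep)
  lo <- min(td) - 18 * 3600
  if (lo < tt[1] || max(td) > tt[length(tt)]) {
    stop(sprintf("weather series does not cover [%s, %s]",
                 format(as.POSIXct(lo, origin = "1970-01-01", tz = "UTC")),
                 format(max(t_dep))), call. = FALSE)
  }
  at <- function(v, x) stats::approx(tt, v, xout = x)$y
  instants <- lapply(c(0, -6, -12, -18) * 3600, function(off) td + off)
  grab <- function(var) sapply(instants, function(x) at(weather[[var]], x))
  g <- lapply(c("cloud", "temp", "precip_rate", "wind_ew", "wind_ns"), grab)
  g <- lapply(g, function(m) matrix(m, nrow = length(td)))
  data.frame(cloud = rowMeans(g[[1]]), temp = rowMeans(g[[2]]),
             ppt = rowSums(g[[3]]), windEW = rowMeans(g[[4]]),
             windNS = rowMeans(g[[5]]))
}

#' Breeding stage from departure date
#'
#' Colony-wide calendar windows, applied year-agnostically: pre-laying
#' 30 April - 19 May, incubation 20 May - 9 June, early chick-rearing
#' 10 - 30 June, late chick-rearing 1 - 21 July. The windows partition the
#' analysis date range with no overlap and no hole. Dates outside them are an
#' error (such trips are excluded upstream).
#'
#' @param date Departure date(s) (`Date`, `POSIXct` or coercible).
#' @return Factor with levels `pre-laying`, `incubation`,
#'   `early chick-rearing`, `late chick-rearing`.
#' @export
#' @examples
#' breeding_stage(as.Date(c("2012-05-19", "2012-05-20", "2012-06-15")))
breeding_stage <- function(date) {
  if (inherits(date, "POSIXct")) date <- as.Date(date, tz = "UTC")
  date <- as.Date(date)
  mmdd <- format(date, "%m-%d")
  stage <- rep(NA_character_, length(date))
  stage[mmdd >= "04-30" & mmdd <= "05-19"] <- "pre-laying"
  stage[mmdd >= "05-20" & mmdd <= "06-09"] <- "incubation"
  stage[mmdd >= "06-10" & mmdd <= "06-30"] <- "early chick-rearing"
  stage[mmdd >= "07-01" & mmdd <= "07-21"] <- "late chick-rearing"
  if (anyNA(stage)) {
    stop("date(s) outside the breeding-stage windows (Apr 30 - Jul 21): ",
         paste(format(date[is.na(stage)]), collapse = ", "), call. = FALSE)
  }
  factor(stage, levels = c("pre-laying", "incubation", "early chick-rearing",
                           "late chick-rearing"))
}

#' Sex from head-plus-bill length
#'
#' Colony-specific discriminant: below 113.5 mm female, above male. Exactly
#' 113.5 mm is indeterminate (the discriminant defines only strict
#' inequalities) and raises an error rather than silently assigning a sex.
#'
#' @param head_bill Head-plus-bill length(s) in millimetres, positive.
#' @return Factor with levels `female`, `male`.
#' @export
sex_from_morphometrics <- function(head_bill) {
  if (any(!is.finite(head_bill) | head_bill <= 0)) {
    stop("head_bill must be positive", call. = FALSE)
  }
  if (any(head_bill == 113.5)) {
    stop("head_bill exactly at the 113.5 mm discriminant is indeterminate", call. = FALSE)
  }
  factor(ifelse(head_bill < 113.5, "female", "male"), levels = c("female", "male"))
}

#' Annotate trips with covariates
#'
#' Builds the analysis table: for each trip, sunrise proximity of the
#' departure ([hours_since_sunrise()] then [sunrise_proximity()]), 24 h
#' weather summaries ([weather_summary()]), breeding stage, year, and sex
#' from the individuals table.
#'
#' @param trips Classified trip table ([classify_trips()]).
#' @param weather A `gf_weather` series.
#' @param individuals Data frame with `individual_id` and `head_bill` (mm).
#' @param colony `c(lon, lat)` used for sunrise times.
#' @return The trip table with `sunrise_prox`, `cloud`, `temp`, `ppt`,
#'   `windEW`, `windNS`, `stage`, `sex` appended.
#' @export
annotate_trips <- function(trips, weather, individuals, colony) {
  tsr <- hours_since_sunrise(trips$departure, colony[1], colony[2])
  trips$sunrise_prox <- sunrise_proximity(tsr)
  trips <- cbind(trips, weather_summary(weather, trips$departure))
  trips$stage <- breeding_stage(trips$departure)
  trips$year <- factor(format(trips$departure, "%Y"))
  idx <- match(trips$individual_id, individuals$individual_id)
  if (anyNA(idx)) {
    stop("individuals table is missing: ",
         paste(unique(trips$individual_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  trips$sex <- sex_from_morphometrics(individuals$head_bill[idx])
  trips
}
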