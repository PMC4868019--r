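## NOAA solar position calculations (the spreadsheet equations of the NOAA
## Solar Calculator, after Meeus). Accurate to well under two minutes at
## temperate latitudes, which is ample for a sunrise-proximity covariate at
## 5-10 minute GPS sampling.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Julian day from POSIXct (UTC)
julian_day <- function(time) {
  as.numeric(time) / 86400 + 2440587.5
}

## Solar declination (deg) and equation of time (minutes) at Julian century T
solar_basis <- function(jc) {
  gml <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  gma <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ceq <- sin(deg2rad(gma)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * gma)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * gma)) * 0.000289
  stl <- gml + ceq
  sal <- stl - 0.00569 - 0.00478 * sin(deg2rad(125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(deg2rad(125.04 - 1934.136 * jc))
  decl <- rad2deg(asin(sin(deg2rad(oc)) * sin(deg2rad(sal))))
  vary <- tan(deg2rad(oc / 2))^2
  eqtime <- 4 * rad2deg(
    vary * sin(2 * deg2rad(gml)) -
      2 * ecc * sin(deg2rad(gma)) +
      4 * ecc * vary * sin(deg2rad(gma)) * cos(2 * deg2rad(gml)) -
      0.5 * vary^2 * sin(4 * deg2rad(gml)) -
      1.25 * ecc^2 * sin(2 * deg2rad(gma))
  )
  list(decl = decl, eqtime = eqtime)
}

#' Sunrise time (UTC) for a date and location
#'
#' NOAA solar-position sunrise: the instant the sun's centre reaches -0.833
#' degrees altitude (accounting for refraction and solar radius). The
#' calculation is iterated so the solar coefficients are evaluated at the
#' event time rather than noon.
#'
#' @param lon,lat Location in WGS84 decimal degrees. Latitudes poleward of 66
#'   degrees are refused: the study's mid-latitude use case never encounters
#'   polar day or night, and the formula would need special-casing there.
#' @param date A `Date` (or something coercible via [as.Date()]): the UTC
#'   calendar day for which sunrise is wanted.
#' @return A `POSIXct` (UTC) sunrise instant, vectorized over inputs.
#' @export
#' @examples
#' sunrise_time(17.97, 57.29, as.Date("2012-06-15"))
sunrise_time <- function(lon, lat, date) {
  date <- as.Date(date)
  n <- max(length(lon), length(lat), length(date))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); date <- rep_len(date, n)
  if (any(abs(lat) >= 66)) {
    stop("sunrise_time() supports |lat| < 66 degrees (no polar day/night)", call. = FALSE)
  }
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  ## first guess: local solar noon minus 6 h
  t_est <- midnight + (720 - 4 * lon) * 60 - 6 * 3600
  for (i in 1:3) {
    jc <- (julian_day(t_est) - 2451545) / 36525
    sb <- solar_basis(jc)
    cosha <- (cos(deg2rad(90.833)) -
                sin(deg2rad(lat)) * sin(deg2rad(sb$decl))) /
      (cos(deg2rad(lat)) * cos(deg2rad(sb$decl)))
    if (any(abs(cosha) > 1)) {
      stop("sun does not rise/set on the requested date at this latitude", call. = FALSE)
    }
    ha <- rad2deg(acos(cosha))
    noon_min <- 720 - 4 * lon - sb$eqtime
    t_est <- midnight + (noon_min - 4 * ha) * 60
  }
  t_est
}

#' Sunrise proximity transform
#'
#' `cos(pi * t / 12)` of signed hours since sunrise, the covariate describing
#' how close a trip departure is to sunrise: 1 at sunrise, 0 at 6 h before or
#' after, -1 at 12 h. Inputs are wrapped into `(-12, 12]` first, so the
#' transform is defined (and even, and bounded in `[-1, 1]`) for any real
#' input.
#'
#' @param t_since_sunrise Signed hours since sunrise.
#' @return Numeric vector in `[-1, 1]`.
#' @export
#' @examples
#' sunrise_proximity(c(0, 6, -6, 12))  # 1, 0, 0, -1
sunrise_proximity <- function(t_since_sunrise) {
  t <- ((t_since_sunrise + 12) %% 24) - 12       # into (-12, 12]... almost
  t[t == -12] <- 12                              # wrap convention: (-12, 12]
  cos(pi * t / 12)
}

#' Signed hours from the nearest sunrise
#'
#' For a departure instant, computes sunrise on the UTC day before, of, and
#' after departure, and returns the signed offset (hours) to the nearest one,
#' which always lies in (-12, 12]. Using the nearest sunrise handles pre-dawn
#' departures (negative offsets) symmetrically.
#'
#' @param time `POSIXct` departure instants (UTC).
#' @param lon,lat Location in decimal degrees.
#' @return Numeric vector of signed hours.
#' @export
hours_since_sunrise <- function(time, lon, lat) {
  stopifnot(inherits(time, "POSIXct"))
  d0 <- as.Date(time, tz = "UTC")
  out <- numeric(length(time))
  cand <- vapply(c(-1L, 0L, 1L), function(k) {
    as.numeric(time) - as.numeric(sunrise_time(lon, lat, d0 + k))
  }, numeric(length(time)))
  cand <- matrix(cand, nrow = length(time))
  pick <- max.col(-abs(cand), ties.method = "first")
  out <- cand[cbind(seq_along(time), pick)] / 3600
  out
}
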