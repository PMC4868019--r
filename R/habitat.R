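## Foraging-point extraction and land/sea classification: the per-trip
## proportion of foraging time on land, and the derived trip class.

#' Extract likely foraging locations from trip fixes
#'
#' A fix is a foraging point iff its speed lies within `[v_low, v_high]` and
#' it is at least `min_dist_km` from the colony. Slow flight, walking and
#' swimming fall under the default 4 m/s cut, while commuting flapping flight
#' lies well above it; the colony-distance rule removes resting and comfort
#' behaviour near the colony. Run on interpolated fixes
#' ([interpolate_trips()]) so that each point represents an equal slice of
#' time.
#'
#' @param fixes Interpolated trip fixes with speeds (see [derive_speed()] if
#'   the logger did not report them).
#' @param colony Numeric `c(lon, lat)` of the colony.
#' @param v_low,v_high Speed window in m/s (defaults 0 and 4).
#' @param min_dist_km Minimum distance from the colony in km (default 3).
#' @return The foraging subset of `fixes` with a `dist_colony_km` column.
#' @export
extract_foraging_points <- function(fixes, colony, v_low = 0, v_high = 4,
                                    min_dist_km = 3) {
  if (is.null(fixes$speed) || anyNA(fixes$speed)) {
    stop("fixes carry missing speeds; run derive_speed() first", call. = FALSE)
  }
  d <- gf_haversine(fixes$lon, fixes$lat, colony[1], colony[2]) / 1000
  keep <- fixes$speed >= v_low & fixes$speed <= v_high & d >= min_dist_km
  out <- fixes[keep, , drop = FALSE]
  out$dist_colony_km <- d[keep]
  rownames(out) <- NULL
  out
}

#' Assign land or sea habitat to foraging points
#'
#' @param points Foraging points from [extract_foraging_points()].
#' @param mask A `gf_mask` land mask; a point on a polygon boundary counts as
#'   land.
#' @return `points` with a `habitat` factor (`"land"`, `"sea"`); the row count
#'   is unchanged.
#' @export
assign_habitat <- function(points, mask) {
  on_land <- point_on_land(points$lon, points$lat, mask)
  points$habitat <- factor(ifelse(on_land, "land", "sea"), levels = c("land", "sea"))
  points
}

#' Summarize foraging habitat per trip
#'
#' Computes, for each trip, the number of foraging points, the number on
#' land, the proportion on land (`p_land`, `NA` when there are no foraging
#' points) and the trip class.
#'
#' @param points Habitat-assigned foraging points ([assign_habitat()]).
#' @param trip_ids Optional character vector of all trip ids, so that trips
#'   with zero foraging points appear as `unclassified` rows.
#' @return Data frame `trip_id`, `n_forage_points`, `n_land`, `p_land`,
#'   `trip_class`.
#' @export
summarize_trips <- function(points, trip_ids = NULL) {
  ids <- if (is.null(trip_ids)) unique(points$trip_id) else trip_ids
  n <- as.integer(table(factor(points$trip_id, levels = ids)))
  nl <- as.integer(tapply(points$habitat == "land",
                          factor(points$trip_id, levels = ids), sum, default = 0L))
  nl[is.na(nl)] <- 0L
  p <- ifelse(n > 0L, nl / n, NA_real_)
  data.frame(trip_id = ids, n_forage_points = n, n_land = nl, p_land = p,
             trip_class = classify_trip(p))
}

#' Classify a trip from its proportion of terrestrial foraging
#'
#' Classes follow the strict printed bounds: `sea` below 0.05, `land` above
#' 0.95, `mixed` in between; exact 0.05 and 0.95 resolve to `mixed` (the
#' bounds "<5%" and ">95%" are strict). An undefined proportion (no foraging
#' points) is `unclassified`.
#'
#' @param p_land Proportion of foraging points on land, in `[0, 1]` or `NA`.
#' @return Factor with levels `land`, `mixed`, `sea`, `unclassified`.
#' @export
#' @examples
#' classify_trip(c(0, 0.05, 0.5, 0.95, 1, NA))
classify_trip <- function(p_land) {
  if (any(!is.na(p_land) & (p_land < 0 | p_land > 1))) {
    stop("p_land outside [0, 1]", call. = FALSE)
  }
  cls <- ifelse(is.na(p_land), "unclassified",
                ifelse(p_land < 0.05, "sea",
                       ifelse(p_land > 0.95, "land", "mixed")))
  factor(cls, levels = c("land", "mixed", "sea", "unclassified"))
}

#' Classify trips end-to-end
#'
#' Convenience wrapper: interpolate segmented trips, extract foraging points,
#' assign habitat, and summarize per trip, merging the result onto the trip
#' table.
#'
#' @param seg Output of [segment_trips()] (after filtering, pass the retained
#'   trip table via `trips`).
#' @param trips Trip table to annotate (defaults to `seg$trips`).
#' @param colony `c(lon, lat)`.
#' @param mask `gf_mask`.
#' @param v_low,v_high,min_dist_km Classification thresholds, see
#'   [extract_foraging_points()].
#' @param step,max_gap_min Interpolation settings, see [interpolate_trips()].
#' @return `trips` with habitat summary columns appended.
#' @export
classify_trips <- function(seg, colony, mask, trips = seg$trips,
                           v_low = 0, v_high = 4, min_dist_km = 3,
                           step = 300, max_gap_min = 45) {
  interp <- interpolate_trips(seg, step = step, max_gap_min = max_gap_min)
  interp <- interp[interp$trip_id %in% trips$trip_id, , drop = FALSE]
  pts <- extract_foraging_points(interp, colony, v_low, v_high, min_dist_km)
  pts <- assign_habitat(pts, mask)
  hab <- summarize_trips(pts, trip_ids = trips$trip_id)
  merge(trips, hab, by = "trip_id", sort = FALSE)
}
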