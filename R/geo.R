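## Great-circle geometry on the WGS84 sphere. All package distances go through
## gf_haversine() so a single Earth radius (IUGG mean, 6371.0088 km) is used
## everywhere.

#' Earth radius used throughout the package (metres)
#' @keywords internal
GF_EARTH_RADIUS_M <- 6371008.8

#' Haversine great-circle distance
#'
#' Distance in metres between points given in WGS84 decimal degrees, on a
#' sphere of radius 6371.0088 km. Inputs are recycled; vectorized.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in metres.
#' @export
#' @examples
#' gf_haversine(17.97, 57.29, 18.10, 57.29)
gf_haversine <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  if (n == 0L) return(numeric(0))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = GF_EARTH_RADIUS_M)
}

#' Destination point along a great circle
#'
#' Point reached from a start position following an initial bearing (degrees
#' clockwise from north) for a distance in metres, on the same sphere as
#' [gf_haversine()].
#'
#' @param lon,lat Start position in decimal degrees.
#' @param bearing Initial bearing, degrees clockwise from north.
#' @param dist_m Distance in metres.
#' @return Data frame with `lon` and `lat`.
#' @export
gf_destination <- function(lon, lat, bearing, dist_m) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing, dist_m, r = GF_EARTH_RADIUS_M)
  data.frame(lon = p[, 1], lat = p[, 2])
}

#' Test whether points fall on land
#'
#' A point counts as land iff it lies inside or on the boundary of any polygon
#' of the mask (boundary-inclusive: an animal standing on the waterline is on
#' land).
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param mask A land mask as returned by [read_mask()] or [simulate_world()]:
#'   a `gf_mask` object (list of polygons, each a two-column lon/lat matrix).
#' @return Logical vector, `TRUE` for land.
#' @export
point_on_land <- function(lon, lat, mask) {
  stopifnot(inherits(mask, "gf_mask"))
  out <- rep(FALSE, length(lon))
  for (poly in mask$polygons) {
    idx <- which(!out)
    if (length(idx) == 0L) break
    out[idx] <- pracma::inpolygon(lon[idx], lat[idx],
                                  poly[, 1], poly[, 2], boundary = TRUE)
  }
  out
}

## Simple ring validity: closed (first == last handled either way), >= 3 unique
## vertices, no self-intersection for the convex shapes the generator emits is
## not re-checked here; we check closure and minimal size.
validate_ring <- function(m) {
  if (!is.matrix(m) || ncol(m) != 2L) stop("polygon ring must be a 2-column matrix", call. = FALSE)
  if (nrow(m) < 3L) stop("polygon ring needs at least 3 vertices", call. = FALSE)
  invisible(m)
}

## Construct a gf_mask from a list of rings (open rings are fine).
gf_mask <- function(polygons, names = NULL) {
  lapply(polygons, validate_ring)
  structure(list(polygons = polygons, names = names), class = "gf_mask")
}

#' @export
print.gf_mask <- function(x, ...) {
  cat("<gf_mask> ", length(x$polygons), " polygon(s)\n", sep = "")
  invisible(x)
}
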