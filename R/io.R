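## Reading and writing the pipeline's file formats: GPS fix CSVs, weather
## CSVs, GeoJSON land masks, trip-record CSVs and fit-report JSON. Parsing is
## strict and auditable: a malformed row is rejected with its line number, and
## input row count always equals accepted + rejected.

parse_utc <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Read a GPS fix table
#'
#' Reads a CSV with columns `individual_id, timestamp_utc, lon, lat` and an
#' optional `speed_ms` column, validates every row, and returns the fixes
#' grouped by individual and sorted by time. Rows with unparseable timestamps,
#' out-of-range coordinates (`|lat| > 90`, `|lon| > 180`) or negative speeds
#' are rejected with a warning naming their line numbers. Duplicate timestamps
#' within an individual are collapsed to the first occurrence, with a warning.
#'
#' @param path Path to the CSV file.
#' @return A data frame of fixes (class `gf_fixes`) sorted by
#'   `(individual_id, timestamp)`, with attribute `rejected` holding a data
#'   frame of rejected line numbers and reasons.
#' @export
read_fixes <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("individual_id", "timestamp_utc", "lon", "lat")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("fix table is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_speed <- "speed_ms" %in% names(raw)
  ts <- parse_utc(raw$timestamp_utc)
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  speed <- if (has_speed) suppressWarnings(as.numeric(raw$speed_ms)) else rep(NA_real_, nrow(raw))
  if (has_speed) speed[!nzchar(trimws(raw$speed_ms))] <- NA_real_

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "bad timestamp"
  reason[is.na(reason) & (is.na(lon) | is.na(lat))] <- "bad coordinate"
  reason[is.na(reason) & (lat < -90 | lat > 90 | lon < -180 | lon > 180)] <- "coordinate out of range"
  reason[is.na(reason) & has_speed & !is.na(speed) & speed < 0] <- "negative speed"

  bad <- which(!is.na(reason))
  ## +1 for the header line so numbers match the file
  rejected <- data.frame(line = bad + 1L, reason = reason[bad])
  if (nrow(rejected)) {
    warning(sprintf("rejected %d row(s): %s", nrow(rejected),
                    paste(sprintf("line %d (%s)", rejected$line, rejected$reason),
                          collapse = "; ")), call. = FALSE)
  }
  keep <- which(is.na(reason))
  fixes <- data.frame(individual_id = raw$individual_id[keep],
                      timestamp = ts[keep], lon = lon[keep], lat = lat[keep],
                      speed = speed[keep])
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]
  dup <- duplicated(fixes[c("individual_id", "timestamp")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate timestamp(s) to first occurrence", sum(dup)),
            call. = FALSE)
    fixes <- fixes[!dup, , drop = FALSE]
  }
  rownames(fixes) <- NULL
  structure(fixes, rejected = rejected, class = c("gf_fixes", "data.frame"))
}

#' Fill missing speeds from consecutive positions
#'
#' Where the logger did not report speed, fills it with the haversine distance
#' between consecutive fixes of the same individual divided by elapsed time,
#' assigned to the later fix. An instrument-reported speed is never
#' overwritten (it carries less quantization error than a derived one at
#' 300 s intervals). A leading fix with no predecessor gets speed 0.
#'
#' @param fixes A fix table as from [read_fixes()] (columns `individual_id`,
#'   `timestamp`, `lon`, `lat`, `speed`).
#' @return The fix table with `speed` filled.
#' @export
derive_speed <- function(fixes) {
  if (!all(c("individual_id", "timestamp", "lon", "lat") %in% names(fixes))) {
    stop("not a fix table", call. = FALSE)
  }
  if (is.null(fixes$speed)) fixes$speed <- NA_real_
  if (!any(is.na(fixes$speed))) return(fixes)
  o <- order(fixes$individual_id, fixes$timestamp)
  f <- fixes[o, ]
  n <- nrow(f)
  sp <- f$speed
  if (n >= 2L) {
    d <- gf_haversine(f$lon[-n], f$lat[-n], f$lon[-1], f$lat[-1])
    dt <- as.numeric(f$timestamp[-1]) - as.numeric(f$timestamp[-n])
    same <- f$individual_id[-1] == f$individual_id[-n]
    derived <- c(NA_real_, ifelse(same & dt > 0, d / dt, NA_real_))
    sp[is.na(sp)] <- derived[is.na(sp)]
  }
  first <- !duplicated(f$individual_id)
  sp[first & is.na(sp)] <- 0
  f$speed <- sp
  rownames(f) <- NULL
  f
}

#' Read a land mask from GeoJSON
#'
#' Accepts a GeoJSON `FeatureCollection` (or bare `Polygon`/`MultiPolygon`
#' geometry) in WGS84 and returns the package's polygon mask. Only outer rings
#' are used; the generator's masks have no holes.
#'
#' @param path Path to a GeoJSON file.
#' @return A `gf_mask` object.
#' @export
read_mask <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- list(); nms <- character()
  grab_geom <- function(geom, name) {
    if (is.null(geom$type)) stop("invalid GeoJSON: geometry without type", call. = FALSE)
    if (geom$type == "Polygon") {
      ring <- geom$coordinates[[1]]
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      polys[[length(polys) + 1L]] <<- m
      nms[length(nms) + 1L] <<- name
    } else if (geom$type == "MultiPolygon") {
      for (pp in geom$coordinates) {
        m <- do.call(rbind, lapply(pp[[1]], function(p) c(p[[1]], p[[2]])))
        polys[[length(polys) + 1L]] <<- m
        nms[length(nms) + 1L] <<- name
      }
    } else {
      stop("invalid GeoJSON: unsupported geometry type ", geom$type, call. = FALSE)
    }
  }
  if (identical(g$type, "FeatureCollection")) {
    for (ft in g$features) {
      nm <- if (!is.null(ft$properties$name)) ft$properties$name else ""
      grab_geom(ft$geometry, nm)
    }
  } else if (identical(g$type, "Feature")) {
    grab_geom(g$geometry, "")
  } else {
    grab_geom(g, "")
  }
  gf_mask(polys, nms)
}

#' Write a land mask to GeoJSON
#'
#' @param mask A `gf_mask` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "gf_mask"))
  features <- lapply(seq_along(mask$polygons), function(i) {
    m <- mask$polygons[[i]]
    if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])  # close ring
    ring <- lapply(seq_len(nrow(m)), function(j) c(m[j, 1], m[j, 2]))
    list(type = "Feature",
         properties = list(name = if (!is.null(mask$names)) mask$names[i] else ""),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a colony weather series
#'
#' CSV with columns `timestamp_utc, cloud, temp, precip_rate, wind_ew,
#' wind_ns`. Timestamps must be strictly increasing and no variable may be
#' missing.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `gf_weather`.
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_utc", "cloud", "temp", "precip_rate", "wind_ew", "wind_ns")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("weather table missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  ts <- parse_utc(w$timestamp_utc)
  if (anyNA(ts)) stop("weather table has unparseable timestamps", call. = FALSE)
  out <- data.frame(timestamp = ts, cloud = w$cloud, temp = w$temp,
                    precip_rate = w$precip_rate, wind_ew = w$wind_ew, wind_ns = w$wind_ns)
  validate_weather(out)
}

validate_weather <- function(w) {
  if (any(diff(as.numeric(w$timestamp)) <= 0)) {
    stop("weather timestamps must be strictly increasing", call. = FALSE)
  }
  if (anyNA(w[c("cloud", "temp", "precip_rate", "wind_ew", "wind_ns")])) {
    stop("weather series has missing values", call. = FALSE)
  }
  if (any(w$cloud < 0 | w$cloud > 100)) stop("cloud cover outside [0, 100]", call. = FALSE)
  if (any(w$precip_rate < 0)) stop("negative precipitation rate", call. = FALSE)
  class(w) <- c("gf_weather", "data.frame")
  w
}

#' @rdname read_weather
#' @param weather A `gf_weather` data frame.
#' @export
write_weather <- function(weather, path) {
  out <- data.frame(timestamp_utc = format_utc(weather$timestamp),
                    cloud = weather$cloud, temp = weather$temp,
                    precip_rate = weather$precip_rate,
                    wind_ew = weather$wind_ew, wind_ns = weather$wind_ns)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read annotated trip records
#'
#' Round-trip stable CSV serialization of the analysis table (one row per
#' trip: response counts plus covariates). `write` then `read` then `write`
#' produces byte-identical files.
#'
#' @param records A trip-record data frame.
#' @param path CSV path.
#' @return `read_trip_records()` returns the data frame; the writer returns
#'   `path` invisibly.
#' @export
write_trip_records <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) out[[nm]] <- format_utc(out[[nm]])
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trip_records
#' @export
read_trip_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("departure", "return_time"), names(rec))) {
    rec[[nm]] <- parse_utc(rec[[nm]])
  }
  rec
}

#' Write a model fit report as JSON
#'
#' Serializes a fitted mixed model (or a ranked model table) to a JSON report
#' mirroring the usual model-selection table: model formula, number of
#' parameters, AICc, delta AICc, marginal and conditional R-squared, variance
#' components and coefficients.
#'
#' @param x A `gf_glmm` fit or the data frame returned by [rank_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(x, path) {
  if (inherits(x, "gf_glmm")) {
    r2 <- r2_nakagawa(x)
    rep <- list(model = deparse(x$formula), converged = x$converged,
                n_obs = x$n_obs, k_params = x$k_params,
                loglik = x$loglik, aicc = aicc(x),
                r2_marginal = r2[["marginal"]], r2_conditional = r2[["conditional"]],
                beta = as.list(x$beta),
                var_components = as.list(x$sigma^2))
  } else {
    rep <- x
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
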