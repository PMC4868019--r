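# brute-force reference: scan the distance series, assign maximal outside runs
brute_segments <- function(dists_m, radius = 500) {
  out <- dists_m > radius
  r <- rle(out)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

nests_for <- function(fx) data.frame(individual_id = unique(fx$individual_id),
                                     nest_lon = 18, nest_lat = 57)

test_that("a track never leaving the radius yields no trips", {
  fx <- walk_fixes(c(0, 100, 300, 450, 200, 0))
  seg <- segment_trips(fx, nests_for(fx))
  expect_equal(nrow(seg$trips), 0L)
  expect_true(all(is.na(seg$fixes$trip_id)))
})

test_that("an in-out(3)-in track yields one trip with exactly the outside fixes", {
  fx <- walk_fixes(c(0, 100, 2000, 4000, 2000, 100, 0))
  seg <- segment_trips(fx, nests_for(fx))
  expect_equal(nrow(seg$trips), 1L)
  expect_equal(sum(!is.na(seg$fixes$trip_id)), 3L)
  tr <- seg$trips
  expect_true(tr$complete)
  ## departure is the midpoint of the bracketing fixes
  expect_equal(as.numeric(tr$departure),
               mean(as.numeric(fx$timestamp[2:3])))
  expect_equal(as.numeric(tr$return_time),
               mean(as.numeric(fx$timestamp[5:6])))
  expect_equal(tr$max_distance_km, 4, tolerance = 1e-3)
})

test_that("segmentation matches the brute-force scan on random tracks", {
  set.seed(99)
  for (rep in 1:20) {
    d <- abs(cumsum(rnorm(sample(20:200, 1), 0, 400)))
    fx <- walk_fixes(d)
    seg <- segment_trips(fx, nests_for(fx))
    ref <- brute_segments(d)
    expect_equal(nrow(seg$trips), nrow(ref))
    if (nrow(ref)) {
      got <- table(seg$fixes$trip_id)
      expect_equal(sort(as.integer(got)),
                   sort(unname(ref[, "end"] - ref[, "start"] + 1L)))
    }
    ## no fix in two trips (each fix has at most one id by construction),
    ## and counts are conserved
    expect_equal(sum(!is.na(seg$fixes$trip_id)) + sum(is.na(seg$fixes$trip_id)),
                 length(d))
  }
})

test_that("a trip still open at track end is incomplete", {
  fx <- walk_fixes(c(0, 100, 2000, 4000, 6000))
  seg <- segment_trips(fx, nests_for(fx))
  expect_equal(nrow(seg$trips), 1L)
  expect_false(seg$trips$complete)
})

test_that("interpolation is the identity on on-grid fixes and bisects off-grid pairs", {
  fx <- walk_fixes(c(0, 100, 2000, 4000, 2000, 100, 0))
  seg <- segment_trips(fx, nests_for(fx))
  interp <- interpolate_trips(seg, step = 300)
  shared <- merge(interp, seg$fixes[!is.na(seg$fixes$trip_id), ],
                  by = "timestamp")
  expect_equal(shared$lon.x, shared$lon.y)
  expect_false(any(interp$interpolated[interp$timestamp %in% seg$fixes$timestamp]))
  ## two fixes 600 s apart -> one midpoint at the coordinate mean
  fx2 <- walk_fixes(c(0, 1000, 3000, 0), step_s = 600)
  seg2 <- segment_trips(fx2, nests_for(fx2))
  i2 <- interpolate_trips(seg2, step = 300)
  mid <- i2[i2$interpolated, ]
  expect_equal(nrow(mid), 1L)
  expect_equal(mid$lon, mean(seg2$fixes$lon[2:3]), tolerance = 1e-10)
})

test_that("no grid points are created inside a long gap", {
  t0 <- as.POSIXct("2012-06-01 06:00:00", tz = "UTC")
  fx <- walk_fixes(c(0, 2000, 3000, 4000), step_s = 300)
  fx$timestamp <- t0 + c(0, 300, 600, 600 + 7200)  # 2 h gap before last fix
  seg <- segment_trips(fx, nests_for(fx))
  interp <- interpolate_trips(seg, step = 300, max_gap_min = 45)
  in_gap <- interp$timestamp > t0 + 600 & interp$timestamp < t0 + 7800
  expect_equal(sum(in_gap), 0L)
})

test_that("filtering excludes with reasons and conserves counts", {
  sc <- small_scenario()
  world <- simulate_world(sc)
  tk <- simulate_tracks(sc, world)
  seg <- segment_trips(derive_speed(tk$fixes), world$nests)
  flt <- filter_trips(seg$trips)
  expect_equal(nrow(flt$trips) + nrow(flt$exclusions), nrow(seg$trips))
  ## a 10-minute trip is excluded for duration
  tr <- seg$trips[1, ]
  tr$duration_h <- 10 / 60; tr$complete <- TRUE
  tr$max_distance_km <- 10; tr$n_fixes <- 20; tr$max_gap_min <- 0
  out <- filter_trips(tr)
  expect_equal(out$exclusions$reason, "min_duration")
  ## every excluded trip's reason is consistent with its metrics
  rules <- filter_config()
  ex <- merge(flt$exclusions, seg$trips, by = "trip_id")
  ok <- mapply(function(reason, dur, dist, nf, gap, comp) {
    switch(reason,
           incomplete = !comp,
           min_duration = dur < rules$min_duration_h,
           min_distance = dist < rules$min_distance_km,
           min_fixes = nf < rules$min_fixes,
           max_gap = gap / 60 > rules$max_gap_frac * dur,
           outside_window = TRUE)
  }, ex$reason, ex$duration_h, ex$max_distance_km, ex$n_fixes, ex$max_gap_min,
     ex$complete)
  expect_true(all(ok))
})

test_that("segmentation is idempotent on its own output", {
  fx <- walk_fixes(c(0, 100, 2000, 4000, 2500, 100, 50, 900, 1500, 200, 0))
  seg1 <- segment_trips(fx, nests_for(fx))
  seg2 <- segment_trips(seg1$fixes[names(fx)], nests_for(fx))
  expect_equal(seg2$trips$departure, seg1$trips$departure)
  expect_equal(seg2$trips$return_time, seg1$trips$return_time)
  expect_equal(seg2$fixes$trip_id, seg1$fixes$trip_id)
})
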