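make_trip_fixes <- function(speeds, dists_m, colony = c(18, 57)) {
  p <- gf_destination(colony[1], colony[2], 90, dists_m)
  data.frame(trip_id = "t1", individual_id = "a",
             timestamp = as.POSIXct("2012-06-01 06:00:00", tz = "UTC") +
               300 * seq_along(speeds),
             lon = p$lon, lat = p$lat, speed = speeds, interpolated = FALSE)
}

test_that("foraging extraction applies both the speed window and the distance rule", {
  colony <- c(18, 57)
  ## all commuting-speed fixes -> none
  fx <- make_trip_fixes(rep(12, 5), seq(4000, 8000, 1000))
  expect_equal(nrow(extract_foraging_points(fx, colony)), 0L)
  ## slow but too close to the colony -> excluded
  fx2 <- make_trip_fixes(2, 1000)
  expect_equal(nrow(extract_foraging_points(fx2, colony)), 0L)
  ## slow and far -> kept
  fx3 <- make_trip_fixes(2, 5000)
  expect_equal(nrow(extract_foraging_points(fx3, colony)), 1L)
  ## missing speeds -> precondition error pointing to derive_speed
  fx4 <- fx3; fx4$speed <- NA
  expect_error(extract_foraging_points(fx4, colony), "derive_speed")
})

test_that("extraction equals a brute-force filter and is monotone in v_high", {
  set.seed(5)
  colony <- c(18, 57)
  for (rep in 1:10) {
    n <- 50
    fx <- make_trip_fixes(runif(n, 0, 15), runif(n, 500, 30000))
    d <- gf_haversine(fx$lon, fx$lat, colony[1], colony[2]) / 1000
    for (vh in c(2, 4, 8)) {
      got <- extract_foraging_points(fx, colony, v_high = vh)
      ref <- fx[fx$speed >= 0 & fx$speed <= vh & d >= 3, ]
      expect_equal(nrow(got), nrow(ref))
    }
    n2 <- vapply(c(1, 2, 4, 6, 15), function(vh)
      nrow(extract_foraging_points(fx, colony, v_high = vh)), 0L)
    expect_true(all(diff(n2) >= 0))
  }
})

test_that("habitat assignment is mask membership with count conservation", {
  mask <- square_mask(18.5, 57, 0.1)
  fx <- make_trip_fixes(rep(1, 4), c(5000, 10000, 30000, 33000))
  pts <- extract_foraging_points(fx, c(18, 57))
  out <- assign_habitat(pts, mask)
  expect_equal(nrow(out), nrow(pts))
  on <- point_on_land(out$lon, out$lat, mask)
  expect_equal(out$habitat == "land", on)
})

test_that("trip summaries compute p_land and flag empty trips unclassified", {
  pts <- data.frame(trip_id = rep(c("t1", "t2"), c(10, 8)),
                    habitat = factor(c(rep("land", 10), rep("land", 4), rep("sea", 4)),
                                     levels = c("land", "sea")))
  s <- summarize_trips(pts, trip_ids = c("t1", "t2", "t3"))
  expect_equal(s$p_land, c(1, 0.5, NA))
  expect_equal(as.character(s$trip_class), c("land", "mixed", "unclassified"))
  expect_equal(s$n_forage_points, c(10L, 8L, 0L))
})

test_that("class bounds are strict with boundary values resolving to mixed", {
  expect_equal(as.character(classify_trip(c(0, 0.04999, 0.05, 0.5, 0.95, 0.95001, 1))),
               c("sea", "sea", "mixed", "mixed", "mixed", "land", "land"))
  expect_equal(as.character(classify_trip(NA_real_)), "unclassified")
  expect_error(classify_trip(1.2), "p_land")
})

test_that("every filtered trip receives exactly one class (partition)", {
  sc <- small_scenario()
  world <- simulate_world(sc)
  tk <- simulate_tracks(sc, world)
  seg <- segment_trips(derive_speed(tk$fixes), world$nests)
  flt <- filter_trips(seg$trips)
  trips <- classify_trips(seg, world$colony, world$mask, trips = flt$trips)
  expect_equal(nrow(trips), nrow(flt$trips))
  expect_false(anyNA(trips$trip_class))
  tab <- table(trips$trip_class)
  expect_equal(sum(tab), nrow(flt$trips))
  expect_equal(unname(tab[["unclassified"]]), sum(trips$n_forage_points == 0))
})

test_that("recovered p_land tracks the generator's land fraction (r >= 0.95)", {
  sc <- small_scenario(seed = 21)
  world <- simulate_world(sc)
  tk <- simulate_tracks(sc, world)
  seg <- segment_trips(derive_speed(tk$fixes), world$nests)
  flt <- filter_trips(seg$trips)
  trips <- classify_trips(seg, world$colony, world$mask, trips = flt$trips)
  trips <- trips[trips$n_forage_points > 0, ]
  ## match recovered trips to truth by individual and nearest departure
  tru <- tk$truth
  idx <- vapply(seq_len(nrow(trips)), function(i) {
    cand <- which(tru$individual_id == trips$individual_id[i])
    cand[which.min(abs(as.numeric(tru$departure[cand]) -
                         as.numeric(trips$departure[i])))]
  }, 0L)
  keep <- abs(as.numeric(tru$departure[idx]) - as.numeric(trips$departure)) < 1800
  expect_gt(mean(keep), 0.95)
  expect_gt(cor(trips$p_land[keep], tru$f_land[idx][keep]), 0.95)
})
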