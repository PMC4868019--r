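# Shared fixtures, all built in code at test time.

# a small, fast scenario: 5 individuals, 1 year, ~60 trips
small_scenario <- function(seed = 11, ...) {
  scenario(seed = seed, n_individuals = 5L, n_years = 1L,
           trips_per_ind_year = 12, ...)
}

# simulate a binomial random-intercept dataset with known parameters
sim_glmm_data <- function(seed, n_groups = 10, n_per = 15, beta = c(-0.5, 0.8),
                          sigma = 1, trials_mean = 12) {
  set.seed(seed)
  g <- factor(rep(seq_len(n_groups), each = n_per))
  x <- stats::rnorm(n_groups * n_per)
  n <- stats::rpois(n_groups * n_per, trials_mean) + 1L
  u <- stats::rnorm(n_groups, 0, sigma)
  eta <- beta[1] + beta[2] * x + u[g]
  data.frame(y = stats::rbinom(length(x), n, stats::plogis(eta)),
             n = n, x = x, g = g)
}

# a square land polygon mask centred on (lon0, lat0), half-side in degrees
square_mask <- function(lon0 = 18, lat0 = 57, half = 0.5) {
  gf_mask(list(rbind(c(lon0 - half, lat0 - half), c(lon0 + half, lat0 - half),
                     c(lon0 + half, lat0 + half), c(lon0 - half, lat0 + half))))
}

# hand-built fix table: one individual stepping east from a nest
walk_fixes <- function(dists_m, t0 = as.POSIXct("2012-06-01 06:00:00", tz = "UTC"),
                       nest = c(18, 57), step_s = 300, id = "b1") {
  p <- t(vapply(dists_m, function(d) {
    if (d == 0) c(nest[1], nest[2]) else
      unlist(gf_destination(nest[1], nest[2], 90, d))
  }, numeric(2)))
  data.frame(individual_id = id,
             timestamp = t0 + step_s * (seq_along(dists_m) - 1),
             lon = p[, 1], lat = p[, 2], speed = 1)
}
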