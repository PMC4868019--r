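## Synthetic agricultural-field survey: 10 roadside transects x 5 fields x
## 3 six-day observation periods x 2 day-halves (morning days 1-3, evening
## days 4-6) = 300 observation rows. Gull presence follows a logistic model
## with vegetation-height and period effects plus nested field-within-transect
## random intercepts; vegetation height rises in median across periods while
## staying highly variable within each period.

#' Field-survey generator configuration defaults
#'
#' The generative model for lesser black-backed gull presence is
#' `logit P(present) = b0 + b_height * z(veg_height) + b_period[p] +
#' u_transect + u_field`, with counts of other species positively coupled to
#' the same field-quality axis so that presence associates with waders and
#' other gulls.
#'
#' @param b0 Intercept on the logit scale (period 1, average field).
#' @param b_height Coefficient of standardized vegetation height.
#' @param b_period Additive effects of periods 2 and 3.
#' @param sd_transect,sd_field Random-intercept SDs.
#' @param height_median_p1 Median vegetation height (cm) in period 1.
#' @param height_growth Multiplicative median growth per period.
#' @param height_sdlog Within-period lognormal spread of heights.
#' @return A list of class `gf_field_config`.
#' @export
field_config <- function(b0 = -0.9, b_height = -1.3, b_period = c(-0.7, -1.4),
                         sd_transect = 0.5, sd_field = 0.8,
                         height_median_p1 = 14, height_growth = 1.5,
                         height_sdlog = 0.55) {
  structure(list(b0 = b0, b_height = b_height, b_period = b_period,
                 sd_transect = sd_transect, sd_field = sd_field,
                 height_median_p1 = height_median_p1,
                 height_growth = height_growth, height_sdlog = height_sdlog),
            class = "gf_field_config")
}

#' Generate a field-observation table
#'
#' Emits the 300-row survey described under [field_config()]: per-row species
#' counts (black-headed gull, common gull, herring gull, lesser black-backed
#' gull, lapwing, oystercatcher), vegetation height (mean of five 1 m
#' quadrats), vegetation-cover class, crop type and earthworm count, plus
#' ground-truth columns (`lp_truth`, `u_field_truth`, `u_transect_truth`).
#'
#' @param sc A [scenario()] (supplies the seed) or a bare integer seed.
#' @param config A [field_config()].
#' @return Data frame of class `gf_field_obs` with 300 rows.
#' @export
simulate_field_observations <- function(sc, config = field_config()) {
  seed <- if (inherits(sc, "gf_scenario")) child_seed(sc$seed, "fields") else as.integer(sc)
  set.seed(seed)
  cfg <- config
  transects <- sprintf("T%02d", 1:10)
  grid <- expand.grid(field_in_transect = 1:5, transect_id = transects,
                      stringsAsFactors = FALSE)
  grid$field_id <- sprintf("%s_F%d", grid$transect_id, grid$field_in_transect)
  crops <- c("cereal", "grass", "roots", "ryegrass", "other")
  field_crop <- sample(crops, 50, replace = TRUE, prob = c(0.35, 0.3, 0.1, 0.15, 0.1))
  u_tr <- stats::setNames(stats::rnorm(10, 0, cfg$sd_transect), transects)
  u_fd <- stats::setNames(stats::rnorm(50, 0, cfg$sd_field), grid$field_id)
  ## field-quality axis couples the bird community (short swards attract all)
  quality <- stats::setNames(stats::rnorm(50, 0, 0.6), grid$field_id)

  obs <- expand.grid(obs_period = 1:3, day = c("morning", "evening"),
                     field_id = grid$field_id, stringsAsFactors = FALSE)
  obs <- obs[order(obs$field_id, obs$obs_period, obs$day), ]
  m <- match(obs$field_id, grid$field_id)
  obs$transect_id <- grid$transect_id[m]
  obs$crop_type <- factor(field_crop[m], levels = crops)

  n <- nrow(obs)
  ## vegetation: five quadrat heights per field-period, means reported
  base <- log(cfg$height_median_p1) + log(cfg$height_growth) * (obs$obs_period - 1)
  quad_h <- matrix(stats::rlnorm(n * 5, rep(base, each = 5), cfg$height_sdlog), ncol = 5,
                   byrow = TRUE)
  quad_c <- matrix(pmin(pmax(stats::rnorm(n * 5,
                                          30 + 1.6 * rep(rowMeans(quad_h), each = 5), 12),
                             0), 100), ncol = 5, byrow = TRUE)
  veg <- summarize_vegetation(quad_h, quad_c)
  obs$veg_height <- veg$veg_height
  obs$veg_cover_class <- veg$veg_cover_class

  zh <- (obs$veg_height - mean(obs$veg_height)) / stats::sd(obs$veg_height)
  lp <- cfg$b0 + cfg$b_height * zh +
    c(0, cfg$b_period)[obs$obs_period] +
    u_tr[obs$transect_id] + u_fd[obs$field_id]
  present <- stats::rbinom(n, 1, stats::plogis(lp))
  obs$lbbg <- ifelse(present == 1, 1 + stats::rpois(n, 1.2), 0)
  ## community counts share the quality axis and the short-sward preference
  lam <- exp(0.35 - 0.55 * zh + quality[obs$field_id] + 0.5 * (present - 0.3))
  obs$black_headed_gull <- stats::rpois(n, lam * 1.6)
  obs$common_gull <- stats::rpois(n, lam * 0.8)
  obs$herring_gull <- stats::rpois(n, lam * 0.5)
  obs$lapwing <- stats::rpois(n, lam * 1.1)
  obs$oystercatcher <- stats::rpois(n, lam * 0.6)
  obs$earthworms <- stats::rpois(n, 3)
  obs$lp_truth <- lp
  obs$u_transect_truth <- unname(u_tr[obs$transect_id])
  obs$u_field_truth <- unname(u_fd[obs$field_id])
  rownames(obs) <- NULL
  obs <- obs[c("transect_id", "field_id", "obs_period", "day", "crop_type",
               "veg_height", "veg_cover_class", "earthworms",
               "black_headed_gull", "common_gull", "herring_gull", "lbbg",
               "lapwing", "oystercatcher",
               "lp_truth", "u_transect_truth", "u_field_truth")]
  class(obs) <- c("gf_field_obs", "data.frame")
  obs
}
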