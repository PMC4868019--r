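## Agricultural-field analysis: derived response and covariates, quadrat
## summaries, and the binomial GLMM model set with field-within-transect
## nested random intercepts.

#' Derive presence and community covariates from field counts
#'
#' Adds `lbbg_present` (1 iff the lesser black-backed gull count is positive),
#' `waders` (lapwing + oystercatcher) and `other_gulls` (black-headed +
#' common + herring gull; all gulls excluding the focal species).
#'
#' @param obs A field-observation table ([simulate_field_observations()] or a
#'   CSV with the same count columns).
#' @return `obs` with the three derived columns appended; row count unchanged.
#' @export
derive_presence <- function(obs) {
  need <- c("lbbg", "lapwing", "oystercatcher", "black_headed_gull",
            "common_gull", "herring_gull")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("field table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  obs$lbbg_present <- as.integer(obs$lbbg > 0)
  obs$waders <- obs$lapwing + obs$oystercatcher
  obs$other_gulls <- obs$black_headed_gull + obs$common_gull + obs$herring_gull
  obs
}

#' Summarize quadrat vegetation measurements
#'
#' Means the five 1 m quadrat heights and covers per field visit; the mean
#' cover is ranked into quarter classes with a lower-inclusive boundary rule
#' (a mean of exactly 50% falls in "50-75%"; 100% belongs to "75-100%").
#'
#' @param heights Numeric matrix (rows = field visits, columns = quadrats) or
#'   vector of 5 heights in cm.
#' @param covers Same shape, percentage cover in `[0, 100]`.
#' @return Data frame with `veg_height` (cm) and `veg_cover_class` (ordered
#'   factor `0-25%`, `25-50%`, `50-75%`, `75-100%`).
#' @export
summarize_vegetation <- function(heights, covers) {
  if (is.null(dim(heights))) heights <- matrix(heights, nrow = 1)
  if (is.null(dim(covers))) covers <- matrix(covers, nrow = 1)
  h <- rowMeans(heights)
  cv <- rowMeans(covers)
  if (any(cv < 0 | cv > 100)) stop("cover outside [0, 100]", call. = FALSE)
  lev <- c("0-25%", "25-50%", "50-75%", "75-100%")
  idx <- pmin(findInterval(cv, c(0, 25, 50, 75), rightmost.closed = FALSE), 4L)
  data.frame(veg_height = h,
             veg_cover_class = factor(lev[idx], levels = lev, ordered = TRUE))
}

#' Default field model set
#'
#' The candidate fixed-effect structures for gull presence on fields, all
#' with `(1 | transect_id/field_id)` nested random intercepts: temporal terms
#' (observation period, morning/evening), vegetation terms (height, cover
#' class, crop type) and their combinations, ranked by AICc.
#'
#' @return Named character vector of fixed-effect right-hand sides.
#' @export
field_model_set <- function() {
  c(intercept = "1",
    day = "day",
    obs.per = "factor(obs_period)",
    "obs.per + day" = "factor(obs_period) + day",
    veg.height = "veg_height",
    "veg.height + veg.cover" = "veg_height + veg_cover_class",
    "crop + veg.height" = "crop_type + veg_height",
    "crop + veg.height + veg.cover" = "crop_type + veg_height + veg_cover_class",
    "veg.height + obs.per" = "veg_height + factor(obs_period)")
}

#' Fit and rank the field presence models
#'
#' Fits each candidate as a Bernoulli GLMM (trials = 1) with nested
#' field-within-transect intercepts via [fit_glmm()], ranks by AICc, and
#' optionally adds the species-association models (earthworms, waders, other
#' gulls added one at a time to the best-ranked structure).
#'
#' @param obs Field table (passed through [derive_presence()] if needed).
#' @param models Named character vector of fixed-effect RHSs
#'   (default [field_model_set()]).
#' @param associations Add association terms to the best model
#'   (default `TRUE`).
#' @return List with `ranking` (data frame from [rank_models()]) and `fits`
#'   (named list of `gf_glmm` objects).
#' @export
fit_field_models <- function(obs, models = field_model_set(),
                             associations = TRUE) {
  if (is.null(obs$lbbg_present)) obs <- derive_presence(obs)
  obs$veg_cover_class <- factor(obs$veg_cover_class, ordered = FALSE)
  fits <- list()
  for (nm in names(models)) {
    fml <- stats::as.formula(paste("lbbg_present ~", models[[nm]],
                                   "+ (1 | transect_id/field_id)"))
    fits[[nm]] <- fit_glmm(fml, obs, se = FALSE)
  }
  rk <- rank_models(fits)
  if (associations) {
    best_rhs <- models[[rk$model[1]]]
    for (assoc in c("earthworms", "waders", "other_gulls")) {
      nm <- paste("best +", assoc)
      fml <- stats::as.formula(paste("lbbg_present ~", best_rhs, "+", assoc,
                                     "+ (1 | transect_id/field_id)"))
      fits[[nm]] <- fit_glmm(fml, obs, se = FALSE)
    }
    rk <- rank_models(fits)
    ## association models are judged against the best base model, not ranked
    base_best <- min(vapply(fits[names(fits) %in% names(models)], aicc, 0))
    rk$dAICc <- rk$AICc - base_best
  }
  list(ranking = rk, fits = fits)
}
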