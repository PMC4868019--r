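## Model-comparison toolkit: AICc, model ranking, Nakagawa-Schielzeth
## R-squared, Gelman-style predictor standardization, collinearity condition
## number, and single-term-deletion likelihood-ratio tests.

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with `k` the number of fixed
#' coefficients plus the number of variance components, and `n` the number of
#' observation rows. Counting variance components in `k` keeps rankings
#' self-consistent across random structures.
#'
#' @param fit A converged `gf_glmm` fit.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "gf_glmm"))
  k <- fit$k_params; n <- fit$n_obs
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * fit$loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank fitted models by AICc
#'
#' @param fits A (possibly named) list of `gf_glmm` fits on the same data.
#' @return Data frame sorted by ascending AICc with columns `model`, `df`,
#'   `AICc`, `dAICc`, `R2m`, `R2c`; the best model has `dAICc = 0`.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "gf_glmm")))
  nm <- names(fits)
  if (is.null(nm)) nm <- rep("", length(fits))
  lab <- vapply(seq_along(fits), function(i) {
    if (nzchar(nm[i])) nm[i] else deparse(fits[[i]]$formula, width.cutoff = 500)
  }, "")
  a <- vapply(fits, aicc, 0)
  r2 <- t(vapply(fits, function(f) r2_nakagawa(f), c(marginal = 0, conditional = 0)))
  out <- data.frame(model = lab, df = vapply(fits, function(f) f$k_params, 0L),
                    AICc = a, dAICc = a - min(a),
                    R2m = r2[, "marginal"], R2c = r2[, "conditional"])
  out <- out[order(out$AICc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marginal and conditional R-squared for logit-link mixed models
#'
#' Variance-partition R-squared: with `s2_f` the variance of the fixed-effect
#' linear predictor over the data, `s2_a` the summed random-intercept
#' variances and `pi^2/3` the logit-link distribution-specific variance,
#' marginal R2 is `s2_f / (s2_f + s2_a + pi^2/3)` and conditional R2 is
#' `(s2_f + s2_a)` over the same denominator.
#'
#' @param fit A converged logit-link `gf_glmm` fit.
#' @return Named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "gf_glmm"))
  s2f <- stats::var(drop(fit$X %*% fit$beta))
  s2a <- sum(fit$sigma^2)
  denom <- s2f + s2a + pi^2 / 3
  c(marginal = s2f / denom, conditional = (s2f + s2a) / denom)
}

#' Standardize predictors for comparable coefficients
#'
#' Gelman-style scaling: numeric predictors are centered and divided by two
#' standard deviations (so a one-unit change spans roughly the variable's
#' 2 SD range and coefficients are comparable with those of binary
#' predictors); binary 0/1 predictors are centered only; factors are left for
#' dummy coding against their reference level. The returned mapping allows
#' coefficients to be back-transformed (`beta_original = beta_std / scale`).
#'
#' @param data Data frame.
#' @param vars Character vector of columns to transform; defaults to all
#'   numeric columns.
#' @return List with `data` (transformed) and `scaling` (data frame `var`,
#'   `center`, `scale`).
#' @export
standardize_predictors <- function(data, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, TRUE)]
  }
  map <- data.frame(var = character(), center = numeric(), scale = numeric())
  for (v in vars) {
    x <- data[[v]]
    if (!is.numeric(x)) stop("cannot standardize non-numeric predictor '", v, "'", call. = FALSE)
    ux <- unique(x[!is.na(x)])
    if (length(ux) <= 1L || stats::sd(x, na.rm = TRUE) == 0) {
      stop("zero-variance predictor '", v, "'", call. = FALSE)
    }
    if (length(ux) == 2L && all(ux %in% c(0, 1))) {
      ctr <- mean(x, na.rm = TRUE); scl <- 1
    } else {
      ctr <- mean(x, na.rm = TRUE); scl <- 2 * stats::sd(x, na.rm = TRUE)
    }
    data[[v]] <- (x - ctr) / scl
    map <- rbind(map, data.frame(var = v, center = ctr, scale = scl))
  }
  list(data = data, scaling = map)
}

#' Collinearity condition number of the fixed-effects design
#'
#' The exact 2-norm condition number (ratio of largest to smallest singular
#' value) of the fixed-effects design matrix including the intercept,
#' conventionally assessed on the standardized model; values below 10 are
#' considered acceptable.
#'
#' @param fit A `gf_glmm` fit (or a numeric design matrix).
#' @return The condition number.
#' @export
kappa_collinearity <- function(fit) {
  X <- if (inherits(fit, "gf_glmm")) fit$X else as.matrix(fit)
  d <- svd(X, nu = 0, nv = 0)$d
  if (min(d) < max(d) * 1e-12) {
    stop("design matrix is rank deficient (kappa is unbounded)", call. = FALSE)
  }
  max(d) / min(d)
}

#' Single-term deletion likelihood-ratio tests
#'
#' Drops each droppable fixed term (respecting marginality: main effects
#' contained in retained interactions are not dropped), refits, and reports
#' the likelihood-ratio chi-square, its degrees of freedom (number of
#' coefficients removed) and the upper-tail p value.
#'
#' @param fit A converged full `gf_glmm` fit.
#' @param data The data frame the model was fitted to.
#' @return Data frame `term`, `chisq`, `df`, `p`; a term whose reduced model
#'   failed to converge carries `NA` for its p value.
#' @export
drop_term_lrt <- function(fit, data) {
  stopifnot(inherits(fit, "gf_glmm"))
  droppable <- stats::drop.scope(fit$fixed_formula)
  if (!length(droppable)) {
    return(data.frame(term = character(), chisq = numeric(), df = integer(),
                      p = numeric()))
  }
  bars <- find_bars(fit$formula[[3]])
  out <- lapply(droppable, function(tm) {
    red_fixed <- stats::update.formula(fit$fixed_formula, paste(". ~ . -", tm))
    red <- red_fixed
    if (length(bars)) {
      barstr <- paste(vapply(bars, function(b) paste0("(", deparse(b), ")"), ""),
                      collapse = " + ")
      red <- stats::as.formula(
        paste(deparse(red_fixed[[2]]), "~",
              paste(deparse(red_fixed[[3]], width.cutoff = 500), collapse = ""),
              "+", barstr))
    }
    rf <- tryCatch(fit_glmm(red, data, se = FALSE), error = function(e) NULL)
    if (is.null(rf) || !rf$converged) {
      return(data.frame(term = tm, chisq = NA_real_,
                        df = fit$k_params - if (is.null(rf)) NA_integer_ else rf$k_params,
                        p = NA_real_))
    }
    chisq <- max(0, 2 * (fit$loglik - rf$loglik))
    df <- fit$k_params - rf$k_params
    data.frame(term = tm, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}
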