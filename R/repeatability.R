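## Individual repeatability of terrestrial-foraging propensity: latent-scale
## intraclass correlation from the fitted model, a randomization p value, and
## a parametric-bootstrap confidence interval.

#' Latent-scale adjusted repeatability from a fitted model
#'
#' For a logit-link binomial mixed model with an individual random intercept,
#' the adjusted repeatability (intraclass correlation once fixed effects are
#' accounted for) on the latent scale is
#' `r = sigma2_ind / (sigma2_ind + pi^2/3)`.
#'
#' @param fit A converged `gf_glmm` fit whose first random term is the
#'   individual intercept.
#' @return Repeatability in `[0, 1]`.
#' @export
repeatability_point <- function(fit) {
  stopifnot(inherits(fit, "gf_glmm"))
  if (!length(fit$sigma)) stop("fit has no random intercept", call. = FALSE)
  s2 <- fit$sigma[1]^2
  unname(s2 / (s2 + pi^2 / 3))
}

#' Randomization p value for repeatability
#'
#' Permutes individual labels across observation rows, refits the model and
#' recomputes repeatability each iteration; the p value uses the plus-one
#' rule `p = (1 + #(r_perm >= r_obs)) / (n_iter + 1)`, so it is never zero
#' and floors at `1/(n_iter+1)`. Iterations whose refit fails to converge are
#' dropped from numerator and denominator (with a warning above 5%).
#'
#' @param fit A converged `gf_glmm` fit with an individual random intercept.
#' @param n_iter Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return The permutation p value, with attribute `r_perm`.
#' @export
randomization_p <- function(fit, n_iter = 1000, seed = NULL) {
  stopifnot(inherits(fit, "gf_glmm"), length(fit$groups) == 1L)
  if (!is.null(seed)) set.seed(seed)
  r_obs <- repeatability_point(fit)
  g <- fit$groups[[1]]
  start <- c(fit$beta, 0.5)  # null data: start sigma small
  r_perm <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    gp <- list(sample(g))
    names(gp) <- names(fit$groups)
    rf <- tryCatch(refit_core(fit$X, fit$y, fit$trials, gp, start),
                   error = function(e) NULL)
    if (!is.null(rf) && rf$converged) {
      r_perm[i] <- rf$sigma[1]^2 / (rf$sigma[1]^2 + pi^2 / 3)
    }
  }
  ok <- !is.na(r_perm)
  if (mean(ok) < 0.95) {
    warning(sprintf("%.1f%% of permutation refits failed to converge",
                    100 * mean(!ok)), call. = FALSE)
  }
  p <- (1 + sum(r_perm[ok] >= r_obs)) / (sum(ok) + 1)
  attr(p, "r_perm") <- r_perm[ok]
  p
}

#' Parametric-bootstrap confidence interval for repeatability
#'
#' Each iteration simulates new responses from the fitted model (fixed
#' effects plus freshly drawn random intercepts plus binomial noise at the
#' observed trial counts), refits, and recomputes repeatability; the interval
#' is the percentile interval of the bootstrap distribution.
#'
#' @param fit A converged `gf_glmm` fit with >= 2 individuals.
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(ci_low =, ci_high =)`, with attribute `r_boot`.
#' @export
bootstrap_ci <- function(fit, n_iter = 1000, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "gf_glmm"), length(fit$groups) >= 1L)
  if (nlevels(fit$groups[[1]]) < 2L) {
    stop("parametric bootstrap requires >= 2 grouping levels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  start <- c(fit$beta, fit$sigma)
  sims <- simulate(fit, nsim = n_iter)
  r_boot <- rep(NA_real_, n_iter)
  for (i in seq_len(n_iter)) {
    rf <- tryCatch(refit_core(fit$X, sims[[i]], fit$trials, fit$groups, start),
                   error = function(e) NULL)
    if (!is.null(rf) && rf$converged) {
      r_boot[i] <- rf$sigma[1]^2 / (rf$sigma[1]^2 + pi^2 / 3)
    }
  }
  ok <- !is.na(r_boot)
  if (mean(ok) < 0.95) {
    warning(sprintf("%.1f%% of bootstrap refits failed to converge",
                    100 * mean(!ok)), call. = FALSE)
  }
  ci <- stats::quantile(r_boot[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  out <- c(ci_low = ci[1], ci_high = ci[2])
  attr(out, "r_boot") <- r_boot[ok]
  out
}

#' Repeatability analysis of a fitted model
#'
#' Combines the point estimate, randomization p value and
#' parametric-bootstrap confidence interval into one result.
#'
#' @param fit A converged `gf_glmm` fit with an individual random intercept.
#' @param n_perm,n_boot Iteration counts (default 1000 each).
#' @param seed RNG seed.
#' @param level Confidence level for the bootstrap interval.
#' @return Object of class `gf_repeatability`: list with `r`,
#'   `p_randomization`, `ci_low`, `ci_high`, `n_perm`, `n_boot`.
#' @export
repeatability <- function(fit, n_perm = 1000, n_boot = 1000, seed = NULL,
                          level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  r <- repeatability_point(fit)
  p <- randomization_p(fit, n_iter = n_perm)
  ci <- bootstrap_ci(fit, n_iter = n_boot, level = level)
  structure(list(r = r, p_randomization = as.numeric(p),
                 ci_low = unname(ci["ci_low"]), ci_high = unname(ci["ci_high"]),
                 n_perm = n_perm, n_boot = n_boot, level = level),
            class = "gf_repeatability")
}

#' @export
print.gf_repeatability <- function(x, ...) {
  cat(sprintf("Repeatability r = %.3f (p = %.4g by randomization, %d iter)\n",
              x$r, x$p_randomization, x$n_perm))
  cat(sprintf("%.0f%% parametric-bootstrap CI: %.3f - %.3f (%d iter)\n",
              100 * x$level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
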