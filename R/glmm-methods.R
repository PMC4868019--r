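## S3 methods for gf_glmm fits.

#' @export
print.gf_glmm <- function(x, digits = 4, ...) {
  cat("Binomial logistic mixed model (", x$method, ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat("  n =", x$n_obs, " logLik =", formatC(x$loglik, digits = digits, format = "f"),
      " AICc =", formatC(x$aicc, digits = digits, format = "f"), "\n")
  if (length(x$sigma)) {
    cat("Random-effect SDs:\n")
    print(round(x$sigma, digits))
  }
  cat("Fixed effects (logit scale):\n")
  print(round(x$beta, digits))
  if (!x$converged) cat("** fit did not converge **\n")
  invisible(x)
}

#' @export
coef.gf_glmm <- function(object, ...) object$beta

#' @export
logLik.gf_glmm <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.gf_glmm <- function(object, ...) {
  if (is.null(object$vcov_beta)) stop("fit was run with se = FALSE", call. = FALSE)
  object$vcov_beta
}

#' @export
fitted.gf_glmm <- function(object, ...) {
  stats::plogis(linpred(object, conditional = TRUE))
}

linpred <- function(object, conditional = TRUE) {
  eta <- drop(object$X %*% object$beta)
  if (conditional && length(object$groups)) {
    for (k in seq_along(object$groups)) {
      eta <- eta + object$u[[k]][as.integer(object$groups[[k]])]
    }
  }
  eta
}

#' @export
residuals.gf_glmm <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  y <- object$y; n <- object$trials
  if (type == "pearson") {
    (y - n * p) / sqrt(n * p * (1 - p))
  } else {
    yy <- pmax(y, 1e-10); nn <- pmax(n - y, 1e-10)
    d2 <- 2 * (y * log(yy / (n * p)) + (n - y) * log(nn / (n * (1 - p))))
    sign(y - n * p) * sqrt(pmax(d2, 0))
  }
}

#' Predict from a fitted binomial mixed model
#'
#' @param object A `gf_glmm` fit.
#' @param newdata Optional data frame; defaults to the fitting data's design.
#' @param type `"link"` (logit scale) or `"response"` (probability).
#' @param re.form `NULL` to include the conditional modes of the random
#'   intercepts (only without `newdata`), `NA` for population-level
#'   predictions.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gf_glmm <- function(object, newdata = NULL,
                            type = c("link", "response"), re.form = NULL, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- linpred(object, conditional = is.null(re.form))
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$beta)
    if (is.null(re.form) && length(object$groups)) {
      for (k in seq_along(object$groups)) {
        gname <- names(object$groups)[k]
        if (gname %in% names(newdata)) {
          lev <- as.character(newdata[[gname]])
          uk <- object$u[[k]][lev]
          uk[is.na(uk)] <- 0
          eta <- eta + uk
        }
      }
    }
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' Simulate responses from a fitted binomial mixed model
#'
#' Parametric simulation: fresh random intercepts are drawn from the fitted
#' variance components, combined with the fixed-effect linear predictor, and
#' binomial noise is added at the observed trial counts. This is the
#' resampling step of the parametric bootstrap.
#'
#' @param object A `gf_glmm` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns of success counts.
#' @export
simulate.gf_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta0 <- drop(object$X %*% object$beta)
  n <- object$trials
  out <- matrix(0L, length(n), nsim)
  for (s in seq_len(nsim)) {
    eta <- eta0
    for (k in seq_along(object$groups)) {
      g <- object$groups[[k]]
      uk <- stats::rnorm(nlevels(g), 0, object$sigma[k])
      eta <- eta + uk[as.integer(g)]
    }
    out[, s] <- stats::rbinom(length(n), n, stats::plogis(eta))
  }
  as.data.frame(out)
}

#' @export
summary.gf_glmm <- function(object, ...) {
  se <- if (!is.null(object$vcov_beta)) sqrt(diag(object$vcov_beta)) else rep(NA_real_, length(object$beta))
  z <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  r2 <- tryCatch(r2_nakagawa(object), error = function(e) c(marginal = NA, conditional = NA))
  structure(list(fit = object, coefficients = tab, r2 = r2), class = "summary.gf_glmm")
}

#' @export
print.summary.gf_glmm <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nWald tests:\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nR2 (marginal / conditional): %.3f / %.3f\n",
              x$r2[["marginal"]], x$r2[["conditional"]]))
  invisible(x)
}
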