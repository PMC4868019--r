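## Binomial logistic mixed models with random intercepts, fitted by maximum
## likelihood with a Laplace approximation to the marginal likelihood.
## Adaptive Gauss-Hermite quadrature (>= 9 nodes) is available as a
## verification mode for single-grouping models. This is the package's own
## estimator: the inner penalized problem is solved by Newton iterations
## (closed-form diagonal solve for a single grouping factor, dense solve for
## nested intercepts), the outer problem by bounded quasi-Newton on
## (beta, log sigma).

## ---- formula utilities -----------------------------------------------------

find_bars <- function(term) {
  if (is.call(term)) {
    if (identical(term[[1]], as.name("|"))) return(list(term))
    if (identical(term[[1]], as.name("(")) ) return(find_bars(term[[2]]))
    out <- list()
    for (i in seq_along(term)[-1]) out <- c(out, find_bars(term[[i]]))
    return(out)
  }
  list()
}

strip_bars <- function(term) {
  if (!is.call(term)) return(term)
  if (identical(term[[1]], as.name("(")) && is.call(term[[2]]) &&
      identical(term[[2]][[1]], as.name("|"))) return(NULL)
  if (identical(term[[1]], as.name("+")) || identical(term[[1]], as.name("-"))) {
    lhs <- strip_bars(term[[2]])
    rhs <- if (length(term) > 2L) strip_bars(term[[3]]) else NULL
    if (is.null(rhs)) return(lhs)
    if (is.null(lhs)) return(if (identical(term[[1]], as.name("+"))) rhs else NULL)
    term[[2]] <- lhs; term[[3]] <- rhs
    return(term)
  }
  term
}

## grouping factors named after their bar expressions; (1|a/b) -> a and a:b
bar_groups <- function(bars, data) {
  groups <- list()
  for (b in bars) {
    if (!identical(b[[2]], 1) && !identical(b[[2]], as.name("1"))) {
      stop("only random intercepts, (1 | group), are supported", call. = FALSE)
    }
    rhs <- b[[3]]
    if (is.call(rhs) && identical(rhs[[1]], as.name("/"))) {
      outer_f <- factor(eval(rhs[[2]], data))
      inner_f <- factor(eval(rhs[[3]], data))
      groups[[deparse(rhs[[2]])]] <- outer_f
      groups[[paste0(deparse(rhs[[2]]), ":", deparse(rhs[[3]]))]] <-
        interaction(outer_f, inner_f, drop = TRUE, sep = ":")
    } else {
      groups[[deparse(rhs)]] <- factor(eval(rhs, data))
    }
  }
  groups
}

## stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- x > 18 & x <= 33.3
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

## ---- deviance function factory ---------------------------------------------

## Returns f(par) = -logLik_Laplace(par), par = c(beta, log sigma_k).
## The inner modes are cached between calls for warm starts.
make_devfun <- function(X, y, n, groups, method = "laplace", nagq = 9L) {
  p <- ncol(X)
  K <- length(groups)
  const <- sum(lchoose(n, y))
  if (K == 0L) {
    return(function(par) {
      eta <- drop(X %*% par)
      -(const + sum(y * eta - n * log1pexp(eta)))
    })
  }
  gidx <- lapply(groups, function(g) as.integer(g))
  qs <- vapply(groups, nlevels, 1L)
  Q <- sum(qs)
  offs <- cumsum(c(0L, qs[-K]))
  single <- K == 1L
  if (single) {
    ## presort rows by group: group sums become cumsum differences, and the
    ## logistic pieces share one exp() call per inner iteration
    o <- order(gidx[[1]])
    X <- X[o, , drop = FALSE]; y <- y[o]; n <- n[o]
    g1 <- gidx[[1]][o]
    ends <- cumsum(tabulate(g1, nbins = qs[1]))
    grpsum <- function(v) diff(c(0, cumsum(v)[ends]))
  } else {
    Z <- matrix(0, nrow(X), Q)
    for (k in seq_len(K)) Z[cbind(seq_len(nrow(X)), offs[k] + gidx[[k]])] <- 1
    g1 <- NULL
  }
  u_cache <- numeric(Q)
  ## variance parameters on the SD scale (bounded below by 0, like lme4's
  ## theta): the profile is smooth there, where the log scale flattens out
  ## and stalls quasi-Newton steps near sigma = 0
  sig_of <- function(par) abs(par[p + seq_len(K)])

  ## p, log(1+e^eta) and the binomial loglik part from a single exp()
  bin_parts <- function(eta) {
    e <- exp(pmin(eta, 30))
    l1pe <- log1p(e)
    pr <- e / (1 + e)
    hi <- eta > 30
    if (any(hi)) { l1pe[hi] <- eta[hi]; pr[hi] <- 1 }
    list(p = pr, ll = sum(y * eta - n * l1pe))
  }

  inner <- function(beta, s2) {
    u <- u_cache
    s2rep <- rep(s2, qs)
    xb <- drop(X %*% beta)
    eta <- xb + if (single) u[g1] else drop(Z %*% u)
    bp <- bin_parts(eta)
    f0 <- bp$ll - sum(u^2 / s2rep) / 2
    for (it in 1:60) {
      mu <- n * bp$p
      w <- mu * (1 - bp$p)
      r <- y - mu
      if (single) {
        grad <- grpsum(r) - u / s2rep
        delta <- grad / (grpsum(w) + 1 / s2rep)
      } else {
        grad <- drop(crossprod(Z, r)) - u / s2rep
        H <- crossprod(Z, Z * w) + diag(1 / s2rep, Q)
        delta <- solve(H, grad)
      }
      if (max(abs(grad)) < 1e-8) break
      step <- 1
      repeat {
        u_new <- u + step * delta
        eta <- xb + if (single) u_new[g1] else drop(Z %*% u_new)
        bp <- bin_parts(eta)
        f1 <- bp$ll - sum(u_new^2 / s2rep) / 2
        if (f1 >= f0 - 1e-12 || step < 1e-4) break
        step <- step / 2
      }
      u <- u_new; f0 <- f1
    }
    w <- n * bp$p * (1 - bp$p)
    if (single) {
      Sw <- grpsum(w)
      logdet <- sum(log1p(s2 * Sw))
      hdiag <- Sw + 1 / s2
    } else {
      M <- crossprod(Z, Z * w)
      sq <- sqrt(rep(s2, qs))
      A <- diag(Q) + (sq %o% sq) * M      # I + D^{1/2} Z'WZ D^{1/2}
      logdet <- 2 * sum(log(diag(chol(A))))
      hdiag <- NULL
    }
    u_cache <<- u
    list(u = u, pen = f0, logdet = logdet, hdiag = hdiag)
  }

  gh <- NULL
  if (method == "agq") {
    if (!single) stop("adaptive quadrature is available for single-grouping models only",
                      call. = FALSE)
    gh <- pracma::gaussHermite(nagq)
  }

  function(par) {
    beta <- par[seq_len(p)]
    s2 <- pmax(sig_of(par)^2, 1e-12)
    fit <- inner(beta, s2)
    if (method == "laplace") {
      return(-(const + fit$pen - fit$logdet / 2))
    }
    ## adaptive Gauss-Hermite, one integral per group
    u_hat <- fit$u
    h <- fit$hdiag                      # curvature at the mode per group
    xb <- drop(X %*% beta)
    sd_node <- sqrt(2 / h)
    ll <- 0
    for (j in seq_len(qs[1])) {
      rows <- which(g1 == j)
      uk <- u_hat[j] + sd_node[j] * gh$x
      terms <- vapply(seq_along(uk), function(k) {
        e <- xb[rows] + uk[k]
        sum(y[rows] * e - n[rows] * log1pexp(e)) +
          stats::dnorm(uk[k], 0, sqrt(s2), log = TRUE)
      }, 0)
      lw <- log(gh$w) + gh$x^2 + terms
      m <- max(lw)
      ll <- ll + m + log(sum(exp(lw - m))) + log(sd_node[j])
    }
    -(const + ll)
  }
}

## ---- user-facing fitting function ------------------------------------------

#' Fit a binomial logistic mixed model with random intercepts
#'
#' Maximum-likelihood estimation of a binomial GLMM with logit link, using a
#' Laplace approximation of the marginal likelihood (`method = "laplace"`,
#' the default) or adaptive Gauss-Hermite quadrature for single-grouping
#' models (`method = "agq"`, a verification mode). Random-effect structure is
#' given lme4-style in the formula: `(1 | individual)` for a single random
#' intercept, `(1 | transect/field)` for nested intercepts. The response may
#' be `cbind(successes, failures)` or a binary vector. Categorical predictors
#' are dummy-coded against their first declared level.
#'
#' @param formula Model formula, e.g.
#'   `cbind(n_land, n_forage_points - n_land) ~ cloud + temp + sunrise_prox + (1 | individual_id)`.
#' @param data Data frame.
#' @param method `"laplace"` or `"agq"`.
#' @param nagq Number of quadrature nodes for `method = "agq"` (>= 9
#'   recommended).
#' @param se Compute a Wald covariance for the fixed effects via a numerical
#'   Hessian (default `TRUE`; refits inside permutation loops switch it off).
#' @param start Optional starting values `c(beta, log sigma)`.
#' @return An object of class `gf_glmm` with components `beta`, `sigma`
#'   (random-effect SDs), `loglik`, `aicc`, `n_obs`, `k_params`, `converged`,
#'   `u` (conditional modes), `vcov_beta`, and the model frame ingredients.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `vcov`, `predict`,
#'   `simulate`, `residuals`, `fitted`.
#' @seealso [aicc()], [rank_models()], [r2_nakagawa()], [drop_term_lrt()],
#'   [kappa_collinearity()], [repeatability()]
#' @export
fit_glmm <- function(formula, data, method = c("laplace", "agq"), nagq = 9L,
                     se = TRUE, start = NULL) {
  method <- match.arg(method)
  bars <- find_bars(formula[[3]])
  fixed <- formula
  rhs <- strip_bars(formula[[3]])
  fixed[[3]] <- if (is.null(rhs)) 1 else rhs
  mf <- stats::model.frame(fixed, data, na.action = stats::na.fail)
  Y <- stats::model.response(mf)
  if (is.matrix(Y)) {
    y <- Y[, 1]; n <- Y[, 1] + Y[, 2]
  } else {
    if (is.factor(Y)) Y <- as.integer(Y) - 1L
    y <- as.numeric(Y); n <- rep(1, length(y))
  }
  if (any(n < 1) || any(y < 0) || any(y > n)) {
    stop("response must satisfy 0 <= successes <= trials, trials >= 1", call. = FALSE)
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  groups <- bar_groups(bars, data)
  for (nm in names(groups)) {
    if (nlevels(groups[[nm]]) < 2L) {
      stop("random term '", nm, "' needs at least 2 grouping levels", call. = FALSE)
    }
  }
  K <- length(groups)
  p <- ncol(X)

  ## starting values: no-random-effect logistic fit
  if (is.null(start)) {
    g0 <- suppressWarnings(stats::glm.fit(X, cbind(y, n - y), family = stats::binomial()))
    start <- c(g0$coefficients, rep(1, K))
  }
  devfun <- make_devfun(X, y, n, groups, method = method, nagq = nagq)
  if (K > 0L) {
    opt <- stats::nlminb(start, devfun,
                         lower = c(rep(-Inf, p), rep(0, K)),
                         upper = c(rep(Inf, p), rep(150, K)),
                         control = list(eval.max = 1000, iter.max = 600,
                                        rel.tol = 1e-10))
    if (opt$convergence != 0) {          # one warm restart from the solution
      opt <- stats::nlminb(opt$par, devfun,
                           lower = c(rep(-Inf, p), rep(0, K)),
                           upper = c(rep(Inf, p), rep(150, K)),
                           control = list(eval.max = 1000, iter.max = 600,
                                          rel.tol = 1e-10))
    }
    par <- opt$par
    converged <- opt$convergence == 0
  } else {
    opt <- stats::nlminb(start, devfun, control = list(rel.tol = 1e-12))
    par <- opt$par
    converged <- opt$convergence == 0
  }
  beta <- stats::setNames(par[seq_len(p)], colnames(X))
  sigma <- stats::setNames(abs(par[p + seq_len(K)]), names(groups))
  loglik <- -devfun(par)
  u <- environment(devfun)$u_cache   # conditional modes at the optimum

  vc <- NULL
  if (se) {
    H <- try(stats::optimHess(par, devfun), silent = TRUE)
    if (!inherits(H, "try-error")) {
      Vi <- try(solve(H), silent = TRUE)
      if (!inherits(Vi, "try-error") && all(diag(Vi)[seq_len(p)] > 0)) {
        vc <- Vi[seq_len(p), seq_len(p), drop = FALSE]
        dimnames(vc) <- list(colnames(X), colnames(X))
      }
    }
  }
  u_list <- NULL
  if (K > 0L) {
    qs <- vapply(groups, nlevels, 1L)
    offs <- cumsum(c(0L, qs[-K]))
    u_list <- lapply(seq_len(K), function(k) {
      stats::setNames(u[offs[k] + seq_len(qs[k])], levels(groups[[k]]))
    })
    names(u_list) <- names(groups)
  }
  fit <- structure(list(
    formula = formula, fixed_formula = fixed, method = method,
    beta = beta, sigma = sigma, loglik = loglik,
    n_obs = length(y), k_params = p + K,
    converged = converged, optim = opt[c("convergence", "message", "iterations")],
    X = X, y = y, trials = n, groups = groups, u = u_list,
    vcov_beta = vc, terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf)),
    class = "gf_glmm")
  fit$aicc <- tryCatch(aicc(fit), error = function(e) NA_real_)
  fit
}

## Minimal refit on prebuilt ingredients; used by permutation and bootstrap
## loops where formula/model.frame overhead would dominate.
refit_core <- function(X, y, n, groups, start) {
  devfun <- make_devfun(X, y, n, groups)
  K <- length(groups); p <- ncol(X)
  opt <- stats::nlminb(start, devfun,
                       lower = c(rep(-Inf, p), rep(0, K)),
                       upper = c(rep(Inf, p), rep(150, K)),
                       control = list(eval.max = 600, iter.max = 400, rel.tol = 1e-9))
  if (opt$convergence != 0) {            # one warm restart from the solution
    opt <- stats::nlminb(opt$par, devfun,
                         lower = c(rep(-Inf, p), rep(0, K)),
                         upper = c(rep(Inf, p), rep(150, K)),
                         control = list(eval.max = 600, iter.max = 400, rel.tol = 1e-9))
  }
  list(beta = opt$par[seq_len(p)], sigma = abs(opt$par[p + seq_len(K)]),
       loglik = -opt$objective, converged = opt$convergence == 0, par = opt$par)
}
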