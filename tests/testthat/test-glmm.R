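test_that("degenerate intercept-only fit recovers the closed-form binomial MLE", {
  d <- data.frame(s = c(3, 5, 2), f = c(7, 5, 8))   # pooled 10 of 30
  fit <- fit_glmm(cbind(s, f) ~ 1, d)
  expect_equal(unname(coef(fit)), qlogis(10 / 30), tolerance = 1e-6)
  expect_equal(fit$k_params, 1L)
})

test_that("Laplace log-likelihood is within 0.1 of adaptive quadrature", {
  for (seed in c(2, 3)) {
    d <- sim_glmm_data(seed, n_groups = sample(c(8, 30, 50), 1))
    fl <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d)
    fq <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d, method = "agq", nagq = 15)
    expect_lt(abs(fl$loglik - fq$loglik), 0.1)
    ## and the quadrature fit agrees on the parameters
    expect_equal(unname(coef(fl)), unname(coef(fq)), tolerance = 0.02)
  }
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  d <- sim_glmm_data(4, n_groups = 12, n_per = 20)
  fit <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d)
  ref <- lme4::glmer(cbind(y, n - y) ~ x + (1 | g), d, family = stats::binomial)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(unname(fit$sigma), sqrt(as.numeric(lme4::VarCorr(ref)$g)),
               tolerance = 1e-3)
})

test_that("a null variance component is estimated at (near) zero", {
  d <- sim_glmm_data(5, n_groups = 19, n_per = 53, sigma = 0, trials_mean = 20)
  fit <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d)
  expect_lt(fit$sigma^2, 0.05)
})

test_that("rank deficiency and degenerate grouping are named errors", {
  d <- sim_glmm_data(6)
  d$x2 <- d$x
  expect_error(fit_glmm(cbind(y, n - y) ~ x + x2 + (1 | g), d), "x2")
  d1 <- d[d$g == "1", ]
  d1$g <- droplevels(d1$g)
  expect_error(fit_glmm(cbind(y, n - y) ~ x + (1 | g), d1), "2 grouping levels")
})

test_that("AICc follows its formula and is undefined for tiny n", {
  fake <- structure(list(loglik = 0, k_params = 2L, n_obs = 10L), class = "gf_glmm")
  expect_equal(aicc(fake), 4 + 12 / 7)
  fake$n_obs <- 3L
  expect_error(aicc(fake), "undefined")
  ## AICc -> AIC as n grows
  fake$n_obs <- 1e6; fake$loglik <- -100
  expect_equal(aicc(fake), 2 * 100 + 2 * 2, tolerance = 1e-4)
})

test_that("model ranking is sorted, zero-based, and order-invariant", {
  d <- sim_glmm_data(7, n_groups = 10, n_per = 20)
  f1 <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d)
  f0 <- fit_glmm(cbind(y, n - y) ~ 1 + (1 | g), d)
  rk <- rank_models(list(full = f1, null = f0))
  expect_equal(rk$dAICc[1], 0)
  expect_true(!is.unsorted(rk$AICc))
  rk2 <- rank_models(list(null = f0, full = f1))
  expect_equal(rk$model, rk2$model)
  expect_equal(rank_models(list(a = f1, b = f1))$dAICc, c(0, 0))
})

test_that("adding an uninformative predictor raises median AICc under the null", {
  set.seed(8)
  deltas <- replicate(60, {
    d <- sim_glmm_data(sample.int(1e6, 1), n_groups = 8, n_per = 10,
                       beta = c(-0.3, 0), sigma = 0.5)
    f0 <- fit_glmm(cbind(y, n - y) ~ 1 + (1 | g), d, se = FALSE)
    f1 <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d, se = FALSE)
    aicc(f1) - aicc(f0)
  })
  expect_gt(median(deltas), 0)
})

test_that("likelihood never decreases when a predictor is added", {
  for (seed in c(9, 10, 11)) {
    d <- sim_glmm_data(seed)
    f0 <- fit_glmm(cbind(y, n - y) ~ 1 + (1 | g), d, se = FALSE)
    f1 <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d, se = FALSE)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
  }
})

test_that("R2 components follow the variance partition", {
  d <- sim_glmm_data(12, n_groups = 12, n_per = 20, sigma = 1)
  fit <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d)
  r2 <- r2_nakagawa(fit)
  expect_lte(r2[["marginal"]], r2[["conditional"]])
  expect_lte(r2[["conditional"]], 1)
  ## sigma == 0 -> marginal equals conditional
  fit0 <- fit_glmm(cbind(s, f) ~ 1, data.frame(s = c(3, 5), f = c(7, 5)))
  r20 <- r2_nakagawa(fit0)
  expect_equal(r20[["marginal"]], r20[["conditional"]])
  ## all-zero fixed effects (intercept-only): marginal = 0
  fitn <- fit_glmm(cbind(y, n - y) ~ 1 + (1 | g), d)
  expect_equal(unname(r2_nakagawa(fitn)[["marginal"]]), 0)
})

test_that("R2 recovers known variance shares in simulation", {
  set.seed(13)
  n_groups <- 40; n_per <- 25
  g <- factor(rep(seq_len(n_groups), each = n_per))
  x <- rnorm(n_groups * n_per)
  beta_x <- 1; sig <- 1.5
  n <- rep(20L, n_groups * n_per)
  y <- rbinom(length(x), n, plogis(beta_x * x + rnorm(n_groups, 0, sig)[g]))
  fit <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), data.frame(y, n, x, g))
  r2 <- r2_nakagawa(fit)
  truth_c <- (beta_x^2 + sig^2) / (beta_x^2 + sig^2 + pi^2 / 3)
  expect_lt(abs(r2[["conditional"]] - truth_c), 0.08)
})

test_that("standardization halves to 2 SD, centers binaries, and keeps a mapping", {
  d <- data.frame(a = c(1, 2, 3, 4), b = c(0, 0, 0, 1), c = rnorm(4))
  out <- standardize_predictors(d, c("a", "b", "c"))
  expect_equal(sd(out$data$a), 0.5)
  expect_equal(sd(out$data$c), 0.5)
  expect_equal(sort(unique(out$data$b)), c(-0.25, 0.75))
  ## a predictor whose SD is 0.5 is centered but keeps its scale
  d2 <- data.frame(z = c(0, 0.5, 1, 0.5, 1, 0))   # sd = 0.4472; general case
  sdz <- sd(d2$z)
  out2 <- standardize_predictors(d2, "z")
  expect_equal(out2$scaling$scale, 2 * sdz)
  expect_equal(out2$data$z, (d2$z - mean(d2$z)) / (2 * sdz))
  expect_error(standardize_predictors(data.frame(k = rep(1, 5)), "k"), "k")
})

test_that("kappa is 1 for orthonormal designs, errors on duplicates, matches svd", {
  Q <- qr.Q(qr(matrix(rnorm(100), 20, 5)))
  expect_equal(kappa_collinearity(Q), 1, tolerance = 1e-10)
  X <- cbind(1, matrix(rnorm(60), 20, 3))
  expect_equal(kappa_collinearity(X),
               max(svd(X)$d) / min(svd(X)$d), tolerance = 1e-8)
  expect_error(kappa_collinearity(cbind(X, X[, 2])), "rank deficient")
})

test_that("single-term deletions respect marginality and count dummy df", {
  d <- sim_glmm_data(14, n_groups = 10, n_per = 24)
  d$f4 <- factor(sample(letters[1:4], nrow(d), TRUE))
  fit <- fit_glmm(cbind(y, n - y) ~ x + f4 + (1 | g), d)
  lrt <- drop_term_lrt(fit, d)
  expect_setequal(lrt$term, c("x", "f4"))
  expect_true(all(lrt$chisq >= 0))
  expect_equal(lrt$df[lrt$term == "f4"], 3L)
  ## a main effect inside an interaction is not droppable
  fit2 <- fit_glmm(cbind(y, n - y) ~ x * f4 + (1 | g), d)
  lrt2 <- drop_term_lrt(fit2, d)
  expect_equal(lrt2$term, "x:f4")
})

test_that("null-term deletion p values are approximately uniform", {
  set.seed(15)
  ps <- replicate(150, {
    d <- sim_glmm_data(sample.int(1e6, 1), n_groups = 8, n_per = 10,
                       beta = c(-0.3, 0), sigma = 0.6)
    fit <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d, se = FALSE)
    drop_term_lrt(fit, d)$p[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("predict and simulate are consistent with the fitted model", {
  d <- sim_glmm_data(16, n_groups = 10, n_per = 20, sigma = 1)
  fit <- fit_glmm(cbind(y, n - y) ~ x + (1 | g), d)
  ## population prediction is the fixed-effect linear predictor
  eta_pop <- predict(fit, re.form = NA)
  expect_equal(eta_pop, drop(fit$X %*% coef(fit)))
  ## conditional response predictions are probabilities
  p <- predict(fit, type = "response")
  expect_true(all(p > 0 & p < 1))
  ## simulate returns counts within trials, reproducible under a seed
  s1 <- simulate(fit, nsim = 3, seed = 1)
  s2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, s2)
  expect_true(all(s1[[1]] >= 0 & s1[[1]] <= fit$trials))
  ## residuals: pearson residuals have finite spread around 0
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 1)
})
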