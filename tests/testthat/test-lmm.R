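test_that("marginal moments follow the random-coefficients structure", {
  p0 <- lmm_params(50, 2, 0, G = matrix(0, 2, 2), sigma2 = 1)
  mm <- marginal_moments(p0, arm = 1, times = c(0, 1))
  expect_equal(mm$mean, c(50, 52))
  expect_equal(mm$cov, diag(2))
  ## hand-computed Z G Z' + s2 I at G = diag(4, 1), t = (0, 2)
  p1 <- lmm_params(0, 0, 0, G = diag(c(4, 1)), sigma2 = 1)
  expect_equal(marginal_moments(p1, 0, c(0, 2))$cov,
               matrix(c(5, 4, 4, 9), 2))
  ## arm difference at time t is beta2 * t exactly
  p2 <- lmm_params(50, 1, -1, G = diag(c(1, 0.1)), sigma2 = 2)
  expect_equal(predict_mean(p2, 1, 10), 50)
  tgrid <- c(0, 2.5, 7)
  expect_equal(predict_mean(p2, 1, tgrid) - predict_mean(p2, 0, tgrid),
               -1 * tgrid)
  expect_equal(predict_mean(lmm_params(0, 0, 0, diag(2), 1), 1, tgrid),
               rep(0, 3))
})

test_that("parameter containers reject invalid inputs", {
  expect_error(lmm_params(0, 0, 0, matrix(c(1, 2, 3, 4), 2), 1), "symmetric")
  expect_error(lmm_params(0, 0, 0, matrix(c(1, 2, 2, 1), 2), 1),
               "semi-definite")
  expect_error(lmm_params(0, 0, 0, diag(2), -1), "sigma2")
})

test_that("observed-data log-likelihood matches a direct MVN oracle", {
  ## single observation at the mean: -log(2*pi)/2
  sch <- visit_schedule(c(0, 1))
  ds1 <- trial_data("a", 0, matrix(c(50, NA), 1), sch)
  p0 <- lmm_params(50, 0, 0, G = matrix(0, 2, 2) + diag(1e-12, 2), sigma2 = 1)
  expect_equal(lmm_loglik(p0, ds1, "ML"), -0.5 * log(2 * pi),
               tolerance = 1e-7)
  ## arbitrary dataset: sum of subject-wise MVN log-densities
  ds <- with_dropout(make_complete_data(n_per_arm = 6, seed = 11),
                     c(4, 3, 2, 4, 1, 3, 4, 4, 2, 3, 4, 1))
  par <- lmm_params(49, 1.7, 0.4, G = matrix(c(5, 0.3, 0.3, 0.4), 2),
                    sigma2 = 1.3)
  direct <- 0
  for (i in seq_along(ds$id)) {
    obs <- which(!is.na(ds$scores[i, ]))
    mm <- marginal_moments(par, ds$arm[i], ds$schedule$times[obs])
    direct <- direct + dmvnorm_log(ds$scores[i, obs], mm$mean, mm$cov)
  }
  expect_equal(lmm_loglik(par, ds, "ML"), as.numeric(direct),
               tolerance = 1e-10)
})

test_that("REML residual variance exceeds the ML estimate", {
  ds <- make_complete_data(n_per_arm = 8, seed = 21, G = diag(c(1e-8, 1e-8)),
                           sigma2 = 4)
  fml <- fit_lmm(ds, "ML")
  frm <- fit_lmm(ds, "REML")
  expect_gt(frm$params$sigma2, fml$params$sigma2)
})

test_that("noise-free linear data are interpolated exactly", {
  sch <- visit_schedule(c(0, 1, 2, 3))
  n <- 6
  arm <- rep(0:1, each = 3)
  y <- 50 + outer(rep(2, n), sch$times)
  ds <- trial_data(sprintf("s%d", 1:n), arm, y, sch)
  f <- fit_lmm(ds, "ML")
  expect_equal(unname(coef(f)), c(50, 2, 0), tolerance = 1e-5)
  expect_lt(f$params$sigma2, 1e-5)
})

test_that("fixed effects equal the GLS solution at the fitted covariance", {
  ds <- with_dropout(make_complete_data(n_per_arm = 10, seed = 31),
                     rep(c(4, 3, 4, 2, 4), 4))
  f <- fit_lmm(ds, "REML")
  ## independent GLS with the fitted variance components plugged in
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_along(ds$id)) {
    obs <- which(!is.na(ds$scores[i, ]))
    tt <- ds$schedule$times[obs]
    X <- cbind(1, tt, ds$arm[i] * tt)
    Z <- cbind(1, tt)
    V <- Z %*% f$params$G %*% t(Z) + diag(f$params$sigma2, length(tt))
    Vi <- solve(V)
    A <- A + t(X) %*% Vi %*% X
    b <- b + t(X) %*% Vi %*% ds$scores[i, obs]
  }
  expect_equal(unname(coef(f)), unname(drop(solve(A, b))), tolerance = 1e-8)
})

test_that("complete balanced data with vanishing G reduce to OLS", {
  ds <- make_complete_data(n_per_arm = 10, seed = 41,
                           G = diag(c(1e-10, 1e-10)), sigma2 = 4)
  f <- fit_lmm(ds, "ML")
  df <- data.frame(y = as.vector(ds$scores),
                   t = rep(ds$schedule$times, each = length(ds$id)),
                   a = rep(ds$arm, times = ds$schedule$J))
  ols <- coef(lm(y ~ t + I(a * t), data = df))
  expect_equal(unname(coef(f)), unname(ols), tolerance = 1e-4)
})

test_that("estimates, SEs and likelihood agree with nlme on one dataset", {
  ds <- with_dropout(make_complete_data(n_per_arm = 30, seed = 51,
                                        G = diag(c(9, 0.5)), sigma2 = 4),
                     sample(rep(c(2, 3, 4, 4), 15)))
  f <- fit_lmm(ds, "REML")
  df <- data.frame(y = as.vector(t(ds$scores)),
                   t = rep(ds$schedule$times, length(ds$id)),
                   a = rep(ds$arm, each = ds$schedule$J),
                   id = rep(ds$id, each = ds$schedule$J))
  df <- df[!is.na(df$y), ]
  ref <- nlme::lme(y ~ t + I(a * t), random = ~ t | id, data = df,
                   method = "REML", control = nlme::lmeControl(opt = "optim"))
  expect_equal(unname(coef(f)), unname(nlme::fixef(ref)), tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  ## Wald z within 2% of the reference implementation
  z_ours <- coef(f) / f$se
  z_ref <- nlme::fixef(ref) / sqrt(diag(vcov(ref)))
  expect_equal(unname(z_ours), unname(z_ref), tolerance = 0.02)
})

test_that("ML optimum dominates random parameter perturbations", {
  ds <- with_dropout(make_complete_data(n_per_arm = 8, seed = 61),
                     rep(c(4, 3, 2, 4), 4))
  f <- fit_lmm(ds, "ML")
  ll0 <- lmm_loglik(f$params, ds, "ML")
  expect_equal(ll0, f$loglik, tolerance = 1e-6)
  set.seed(62)
  for (r in 1:10) {
    eps <- rnorm(3, 0, 0.2)
    pert <- lmm_params(coef(f)[1] + eps[1], coef(f)[2] + eps[2],
                       coef(f)[3] + eps[3], f$params$G,
                       f$params$sigma2 * exp(rnorm(1, 0, 0.1)))
    expect_lt(lmm_loglik(pert, ds, "ML"), ll0 + 1e-8)
  }
})
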