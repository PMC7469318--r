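lmm_ref <- lmm_params(60, 0.5, -0.15, G = matrix(c(300, -2, -2, 0.5), 2),
                      sigma2 = 100)

test_that("current value is the error-free trajectory", {
  p <- lmm_params(50, 1, 0, diag(2), 1)
  expect_equal(current_value(p, c(0, 0), 0, 4), 54)
  ## slope cancellation: beta1 + beta2 + b1 = 0 in the experimental arm
  p2 <- lmm_params(50, 1, -2, diag(2), 1)
  expect_equal(current_value(p2, c(3, 1), 1, c(0, 5, 10)), rep(53, 3))
  ## b = 0 recovers the marginal mean
  tt <- c(0, 2, 7)
  expect_equal(current_value(lmm_ref, c(0, 0), 1, tt),
               unname(predict_mean(lmm_ref, 1, tt)))
})

test_that("hazard follows the piecewise proportional-hazards form", {
  sp <- spm_params(lmm_ref, gamma = 0, alpha = 0, xi = seq(0.1, 0.7, 0.1))
  ## alpha = gamma = 0: hazard equals the baseline level of the interval
  expect_equal(spm_hazard(sp, c(0, 0), 1, c(0, 1.24, 1.25, 35, 36)),
               c(0.1, 0.1, 0.2, 0.7, 0.7))
  ## flat trajectory at 50 with alpha = 0.01: 0.1 * exp(0.5)
  pflat <- lmm_params(50, 0, 0, matrix(0, 2, 2) + diag(1e-12, 2), 1)
  spf <- spm_params(pflat, gamma = 0, alpha = 0.01, xi = rep(0.1, 7))
  expect_equal(spm_hazard(spf, c(0, 0), 0, 3.7), 0.1 * exp(0.5),
               tolerance = 1e-9)
  expect_equal(round(spm_hazard(spf, c(0, 0), 0, 3.7), 5), 0.16487)
  ## proportionality in gamma
  spg <- spm_params(lmm_ref, gamma = log(2), alpha = 0.004, xi = rep(0.2, 7))
  spg0 <- spm_params(lmm_ref, gamma = 0, alpha = 0.004, xi = rep(0.2, 7))
  tt <- c(0.3, 5, 20)
  expect_equal(spm_hazard(spg, c(1, 0.1), 1, tt),
               2 * spm_hazard(spg0, c(1, 0.1), 1, tt))
})

test_that("closed-form cumulative hazard matches numerical integration", {
  ## exponential special case
  sp0 <- spm_params(lmm_ref, gamma = 0, alpha = 0, xi = rep(0.1, 7))
  expect_equal(cumulative_hazard(sp0, c(0, 0), 0, 4), 0.4, tolerance = 1e-12)
  ## linear trajectory 40 + 5t on a constant baseline: the worked value
  plin <- lmm_params(40, 5, 0, matrix(0, 2, 2) + diag(1e-12, 2), 1)
  spl <- spm_params(plin, gamma = 0, alpha = 0.01, xi = rep(0.1, 7))
  expect_equal(round(cumulative_hazard(spl, c(0, 0), 0, 2), 4), 0.3138)
  ## random instances against integrate()
  set.seed(161)
  for (r in 1:6) {
    sp <- spm_params(lmm_ref, gamma = rnorm(1, 0, 0.3),
                     alpha = rnorm(1, 0, 0.02),
                     xi = runif(7, 0.02, 0.5))
    b <- c(rnorm(1, 0, 15), rnorm(1, 0, 0.6))
    a <- rbinom(1, 1, 0.5)
    tt <- runif(1, 0.2, 36)
    num <- integrate(function(u) spm_hazard(sp, b, a, u), 0, tt,
                     subdivisions = 2000L, rel.tol = 1e-12)$value
    expect_equal(cumulative_hazard(sp, b, a, tt), num, tolerance = 1e-8)
    ## survival function is a proper non-increasing probability
    grid <- seq(0, 36, length.out = 25)
    S <- exp(-cumulative_hazard(sp, b, a, grid))
    expect_true(all(S > 0 & S <= 1))
    expect_true(all(diff(S) <= 1e-12))
  }
})

test_that("hazard-ratio transform reproduces the published interpretation", {
  hr <- dropout_hazard_ratio(-0.015, -10, ci = c(-0.03, 0))
  expect_equal(round(as.numeric(hr), 2), 1.16)
  expect_equal(round(attr(hr, "ci"), 2), c(1.00, 1.35))
  expect_equal(round(exp(-0.03 * -10), 4), 1.3499)
  expect_equal(dropout_hazard_ratio(0, 25), 1)
})

test_that("dropout times use the last-available-visit convention", {
  ds <- with_dropout(make_complete_data(n_per_arm = 2,
                                        times = c(0, 1.25, 3, 4, 6, 12, 24, 36)),
                     c(1, 8, 4, 8))
  dt <- derive_dropout_times(ds)
  expect_equal(dt$time, c(0, 36, 4, 36))
  expect_equal(dt$event, c(1L, 0L, 1L, 0L))
})

test_that("joint likelihood decouples exactly at alpha = 0", {
  cfg <- sim_config(n_per_arm = 40, mechanism = "mcar", seed = 171)
  tr <- simulate_trial(cfg)
  ds <- tr$dataset
  dt <- derive_dropout_times(ds)
  set.seed(172)
  for (r in 1:4) {
    par <- lmm_params(rnorm(1, 60, 2), rnorm(1, 0.5, 0.2), rnorm(1, 0, 0.2),
                      G = matrix(c(250, -1, -1, 0.4), 2),
                      sigma2 = runif(1, 60, 140))
    gam <- rnorm(1, 0, 0.3)
    xi <- runif(7, 0.03, 0.4)
    sp <- spm_params(par, gamma = gam, alpha = 0, xi = xi)
    ll <- spm_loglik(sp, ds, nodes = 9)
    ## independent piecewise-exponential survival log-likelihood
    starts <- c(0, sp$knots); ends <- c(sp$knots, Inf)
    surv <- 0
    for (i in seq_along(dt$time)) {
      qi <- findInterval(dt$time[i], sp$knots) + 1
      if (dt$event[i] == 1) surv <- surv + log(xi[qi]) + gam * dt$arm[i]
      for (q in seq_len(qi)) {
        u <- min(ends[q], dt$time[i])
        if (u > starts[q]) surv <- surv - xi[q] * exp(gam * dt$arm[i]) *
            (u - starts[q])
      }
    }
    expect_equal(ll, lmm_loglik(par, ds, "ML") + surv, tolerance = 1e-6)
  }
})

test_that("quadrature is stable between 9 and 25 nodes", {
  hp <- spm_params(lmm_ref, gamma = 0.2, alpha = -0.02, xi = rep(0.25, 7))
  cfg <- sim_config(n_per_arm = 25, mechanism = "mnar_spm",
                    mech_params = hp, seed = 181)
  tr <- simulate_trial(cfg)
  l9 <- spm_loglik(hp, tr$dataset, nodes = 9)
  l25 <- spm_loglik(hp, tr$dataset, nodes = 25)
  expect_lt(abs(l9 - l25), 1e-4)
})

test_that("vanishing random effects collapse the integral to b = 0", {
  cfg <- sim_config(n_per_arm = 10, mechanism = "mcar", seed = 191,
                    lmm = lmm_params(60, 0.5, -0.15,
                                     G = diag(c(1e-8, 1e-10)), sigma2 = 100))
  tr <- simulate_trial(cfg)
  ds <- tr$dataset
  par <- lmm_params(60, 0.5, -0.15, G = diag(c(1e-8, 1e-10)), sigma2 = 100)
  sp <- spm_params(par, gamma = 0.1, alpha = 0.005, xi = rep(0.1, 7))
  ll <- spm_loglik(sp, ds, nodes = 9)
  dt <- derive_dropout_times(ds)
  manual <- lmm_loglik(par, ds, "ML")  # G ~ 0: independent residuals
  for (i in seq_along(dt$time)) {
    if (dt$event[i] == 1) {
      manual <- manual + log(spm_hazard(sp, c(0, 0), ds$arm[i], dt$time[i]))
    }
    manual <- manual - cumulative_hazard(sp, c(0, 0), ds$arm[i], dt$time[i])
  }
  expect_equal(ll, as.numeric(manual), tolerance = 1e-6)
})

test_that("analytic gradient agrees with finite differences", {
  hp <- spm_params(lmm_ref, gamma = 0.2, alpha = -0.02, xi = rep(0.25, 7))
  cfg <- sim_config(n_per_arm = 30, mechanism = "mnar_spm",
                    mech_params = hp, seed = 201)
  tr <- simulate_trial(cfg)
  pre <- qoldrop:::spm_prepare(tr$dataset, sim_dropout_times(tr))
  pre$exposure <- qoldrop:::spm_exposure(pre$T, hp$knots)
  cen <- qoldrop:::spm_centering(lmm_ref, tr$dataset)
  gh <- qoldrop:::gh_rule2(9)
  ex <- pre$exposure
  qTv <- qoldrop:::hazard_interval(pre$T, hp$knots)
  fg <- function(par) qoldrop:::spm_loglik_grad_cpp(
    pre$stats, pre$arm, pre$T, as.integer(pre$event), qTv,
    attr(ex, "ptr"), as.integer(ex[, "q"]), ex[, "l"], ex[, "u"],
    cen$modes, cen$B, cen$logdetB, gh$x1, gh$x2, gh$logw, gh$xsq,
    par[1:3], par[4:7], par[8], par[9], par[9 + 1:7])
  par0 <- c(59, 0.4, -0.1, qoldrop:::vc_to_theta(lmm_ref$G, 90),
            0.15, -0.015, log(rep(0.2, 7)))
  g_an <- drop(fg(par0)$gradient)
  g_num <- sapply(seq_along(par0), function(i) {
    h <- 1e-6 * max(abs(par0[i]), 1)
    pp <- par0; pp[i] <- pp[i] + h
    pm <- par0; pm[i] <- pm[i] - h
    (fg(pp)$value - fg(pm)$value) / (2 * h)
  })
  expect_equal(g_an, g_num, tolerance = 1e-4)
  ## value agrees with the plain likelihood core
  expect_equal(fg(par0)$value,
               qoldrop:::spm_loglik_core(par0[1:3],
                                         qoldrop:::theta_to_vc(par0[4:7])$G,
                                         exp(par0[7]), par0[8], par0[9],
                                         exp(par0[9 + 1:7]), hp$knots,
                                         pre, cen, gh),
               tolerance = 1e-8)
})

test_that("fit without events degenerates to the LMM with a warning", {
  ds <- make_complete_data(n_per_arm = 8, seed = 211,
                           times = c(0, 1.25, 3, 4, 6, 12, 24, 36))
  expect_warning(f <- fit_spm(ds), "no dropout events")
  ml <- fit_lmm(ds, "ML")
  expect_equal(unname(coef(f)[1:3]), unname(coef(ml)), tolerance = 1e-6)
  expect_true(f$degenerate)
})

test_that("constant-hazard data recover the baseline level", {
  hp <- spm_params(lmm_ref, gamma = 0, alpha = 0, xi = rep(0.05, 7))
  ests <- sapply(1:4, function(r) {
    cfg <- sim_config(n_per_arm = 250, mechanism = "mnar_spm",
                      mech_params = hp, seed = 6000 + r)
    tr <- simulate_trial(cfg)
    f <- fit_spm(tr$dataset, dropout = sim_dropout_times(tr), se = FALSE)
    mean(f$params$xi)
  })
  expect_lt(abs(mean(ests) - 0.05), 2 * sd(ests) / 2 + 0.01)
})
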