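test_that("pattern scheme validates and maps dropout indices", {
  sc <- pattern_scheme()
  expect_equal(sc$K, 4L)
  expect_equal(sc$map, c(1L, 1L, 1L, 2L, 2L, 3L, 4L, 4L))
  expect_error(pattern_scheme(list(1:3, 5:8), J = 8), "partition")
  sc2 <- pattern_scheme(list(1:4, 5:8), J = 8)
  expect_equal(sc2$map, rep(1:2, each = 4L))
})

test_that("pattern proportions reproduce the published QL distribution", {
  ## 89/70/58/35 of 252 under the default scheme -> 35/28/23/14 percent
  counts <- c(89, 70, 58, 35)
  D <- rep(c(2, 4, 6, 7), counts)  # one dropout index within each pattern set
  sch <- visit_schedule()
  ds <- with_dropout(trial_data(sprintf("q%03d", 1:252),
                                rep(0:1, length.out = 252),
                                matrix(50, 252, 8), sch), D)
  pat <- assign_patterns(ds, pattern_scheme())
  expect_equal(pat$n_k, counts)
  expect_equal(floor(pat$pi * 100 + 0.5), c(35, 28, 23, 14))
  ## multinomial covariance formula
  expect_equal(pat$vcov_pi, (diag(pat$pi) - tcrossprod(pat$pi)) / 252)
})

test_that("one subject per pattern gives the textbook multinomial covariance", {
  sch <- visit_schedule()
  ds <- with_dropout(trial_data(c("a", "b", "c", "d"), c(0, 1, 0, 1),
                                matrix(50, 4, 8), sch), c(1, 4, 6, 8))
  pat <- assign_patterns(ds)
  expect_equal(pat$pi, rep(0.25, 4))
  expect_equal(diag(pat$vcov_pi), rep(3 / 64, 4))
})

test_that("all-completer data put everyone in the last pattern", {
  ds <- make_complete_data(n_per_arm = 3, times = c(0, 1, 2, 3, 4, 5, 6, 7))
  expect_warning(pat <- assign_patterns(ds, pattern_scheme()), "empty")
  expect_equal(pat$pi, c(0, 0, 0, 1))
})

test_that("a one-pattern scheme reduces the PMM to the plain LMM", {
  ds <- with_dropout(make_complete_data(n_per_arm = 12, seed = 121,
                                        times = c(0, 1, 2, 3, 4, 5, 6, 7)),
                     rep(c(8, 5, 7, 8), 6))
  f1 <- fit_pmm(ds, pattern_scheme(list(1:8), J = 8))
  f0 <- fit_lmm(ds, "REML")
  expect_equal(unname(f1$coef_k[1, ]), unname(coef(f0)), tolerance = 1e-6)
  expect_equal(f1$marginal$estimate, unname(coef(f0)), tolerance = 1e-6)
  ## K = 1 marginalization is the identity, SE unchanged
  expect_equal(f1$marginal$se, unname(f0$se), tolerance = 1e-6)
})

test_that("marginalization is the proportion-weighted sum with delta-method SE", {
  ## hand-built fit object carrying the published QL pattern slopes
  slopes <- c(-2.611, -0.649, -0.009, 0.477)
  pi_hat <- c(89, 70, 58, 35) / 252
  fit <- structure(list(
    coef_k = cbind(beta0 = rep(60, 4), beta1 = slopes, beta2 = rep(0, 4)),
    vcov_k = matrix(0, 12, 12),
    coef_names = unlist(lapply(1:4, function(k)
      paste0(c("beta0_", "beta1_", "beta2_"), k))),
    pi = pi_hat, vcov_pi = matrix(0, 4, 4),
    n = 252), class = c("qol_pmm", "qol_fit"))
  marg <- marginalize_pmm(fit)
  expect_equal(marg["beta1", "estimate"], sum(slopes * pi_hat),
               tolerance = 1e-12)
  expect_equal(round(marg["beta1", "estimate"], 3), -1.038)
  ## zero coefficient and proportion uncertainty -> zero SE
  expect_equal(marg["beta1", "se"], 0)
  ## linearity in the pattern effects at fixed proportions
  fit2 <- fit
  fit2$coef_k[, "beta1"] <- 2 * slopes + 1
  marg2 <- marginalize_pmm(fit2)
  expect_equal(marg2["beta1", "estimate"],
               2 * marg["beta1", "estimate"] + 1, tolerance = 1e-12)
  ## degenerate proportions: the single-pattern variance passes through
  fit3 <- fit
  fit3$pi <- c(1, 0, 0, 0)
  fit3$vcov_k[2, 2] <- 4  # var of beta1 in pattern 1
  expect_equal(marginalize_pmm(fit3)["beta1", "se"], 2)
})

test_that("pattern-homogeneous data give pattern effects matching the LMM", {
  set.seed(131)
  agree <- 0
  for (r in 1:5) {
    cfg <- sim_config(n_per_arm = 100, mechanism = "mcar",
                      seed = 4000 + r)
    tr <- simulate_trial(cfg)
    fp <- fit_pmm(tr$dataset)
    fl <- fit_lmm(tr$dataset)
    z <- abs(fp$marginal["beta1", "estimate"] - coef(fl)[2]) /
      sqrt(fp$marginal["beta1", "se"]^2 + fl$se[2]^2)
    agree <- agree + (z < 2)
  }
  expect_gte(agree, 4)
})

test_that("a pattern-specific slope shift is recovered", {
  mp <- list(pi = c(0.35, 0.25, 0.2, 0.2),
             scheme = pattern_scheme(),
             shifts = cbind(beta0 = rep(0, 4), beta1 = c(-3, 0, 0, 0),
                            beta2 = rep(0, 4)))
  ests <- sapply(1:5, function(r) {
    cfg <- sim_config(n_per_arm = 200, mechanism = "pattern",
                      mech_params = mp, seed = 5000 + r)
    tr <- simulate_trial(cfg)
    f <- fit_pmm(tr$dataset)
    f$coef_k[1, "beta1"]
  })
  truth <- 0.5 - 3  # base control slope plus the pattern-1 shift
  expect_lt(abs(mean(ests) - truth), 2 * sd(ests) / sqrt(5) + 0.2)
})

test_that("stratified variance mode matches per-pattern LMM fits", {
  ds <- with_dropout(make_complete_data(n_per_arm = 20, seed = 141,
                                        times = c(0, 1, 2, 3, 4, 5, 6, 7)),
                     rep(c(3, 8, 5, 8), 10))
  sc <- pattern_scheme(list(1:3, 4:5, 6:8), J = 8)
  fs <- fit_pmm(ds, sc, variance_mode = "stratified")
  ## pattern 3 refit directly on its own subjects
  sel <- sc$map[ds$dropout] == 3
  ds3 <- trial_data(ds$id[sel], ds$arm[sel], ds$scores[sel, ], ds$schedule)
  f3 <- fit_lmm(ds3, "REML")
  expect_equal(unname(fs$coef_k[3, ]), unname(coef(f3)), tolerance = 1e-6)
})

test_that("arm-specific weighting is available and differs when arms differ", {
  cfg <- sim_config(n_per_arm = 80, mechanism = "mar_dk", seed = 151)
  tr <- simulate_trial(cfg)
  f <- fit_pmm(tr$dataset)
  by_arm <- marginalize_pmm(f, weights = "by_arm")
  expect_equal(rownames(by_arm), c("beta0", "beta1", "beta2"))
  expect_true(all(is.finite(by_arm$se)))
})
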