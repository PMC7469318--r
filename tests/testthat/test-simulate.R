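test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(n_per_arm = 30, mechanism = "mnar_dk", seed = 99)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$dataset$scores, t2$dataset$scores)
  expect_identical(t1$dataset$dropout, t2$dataset$dropout)
  expect_identical(t1$random_effects, t2$random_effects)
  ## a different seed changes the data
  t3 <- simulate_trial(sim_config(n_per_arm = 30, mechanism = "mnar_dk",
                                  seed = 100))
  expect_false(identical(t1$dataset$scores, t3$dataset$scores))
})

test_that("noise-free configuration puts every subject on the arm lines", {
  cfg <- sim_config(n_per_arm = 5, mechanism = "none",
                    lmm = lmm_params(50, 2, -1,
                                     G = matrix(0, 2, 2) + diag(1e-18, 2),
                                     sigma2 = 1e-18),
                    seed = 1)
  tr <- simulate_trial(cfg)
  tt <- cfg$schedule$times
  for (i in seq_len(10)) {
    expect_equal(unname(tr$dataset$scores[i, ]),
                 50 + (2 - tr$dataset$arm[i]) * tt, tolerance = 1e-6)
  }
})

test_that("baseline mean matches truth at large n", {
  cfg <- sim_config(n_per_arm = 5000, mechanism = "none", seed = 7)
  tr <- simulate_trial(cfg)
  y0 <- tr$complete_scores[, 1]
  se <- sd(y0) / sqrt(length(y0))
  expect_lt(abs(mean(y0) - 60), 3 * se)
})

test_that("the observed dataset is a deterministic mask of complete scores", {
  for (mech in c("mcar", "mar_dk", "mnar_dk", "mnar_spm", "pattern")) {
    cfg <- sim_config(n_per_arm = 25, mechanism = mech, seed = 11)
    tr <- simulate_trial(cfg)
    J <- cfg$schedule$J
    for (i in seq_along(tr$dataset$id)) {
      D <- tr$dataset$dropout[i]
      expect_equal(unname(tr$dataset$scores[i, 1:D]),
                   unname(tr$complete_scores[i, 1:D]))
      if (D < J) expect_true(all(is.na(tr$dataset$scores[i, (D + 1):J])))
    }
    ## monotone by construction: availability non-increasing over visits
    avail <- colSums(!is.na(tr$dataset$scores))
    expect_true(all(diff(avail) <= 0))
  }
})

test_that("score-blind dropout times are geometric", {
  cfg <- sim_config(n_per_arm = 2500, mechanism = "mcar",
                    mech_params = dk_params(0, 0, 0), seed = 13)
  tr <- simulate_trial(cfg)
  ## psi = 0: each of the 7 opportunities is a fair coin
  D <- tr$dataset$dropout
  n <- length(D)
  for (j in 1:7) {
    at_risk <- sum(D >= j)
    p_hat <- sum(D == j) / at_risk
    expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / at_risk))
  }
})

test_that("informative dropout selects on the unobserved next score", {
  ## psi2 < 0: dropout favours LOW current scores
  cfg <- sim_config(n_per_arm = 2500, mechanism = "mnar_dk",
                    mech_params = dk_params(1.5, 0, -0.05), seed = 17)
  tr <- simulate_trial(cfg)
  y2 <- tr$complete_scores[, 2]
  dropped <- tr$dataset$dropout == 1
  expect_gt(mean(y2[!dropped]) - mean(y2[dropped]), 0)
  ## and the reverse for psi2 > 0
  cfg2 <- sim_config(n_per_arm = 2500, mechanism = "mnar_dk",
                     mech_params = dk_params(-4.5, 0, 0.05), seed = 18)
  tr2 <- simulate_trial(cfg2)
  y2b <- tr2$complete_scores[, 2]
  d2 <- tr2$dataset$dropout == 1
  expect_gt(mean(y2b[d2]) - mean(y2b[!d2]), 0)
})

test_that("continuous-time dropout follows the subject-specific hazard", {
  lmmT <- lmm_params(60, 0.5, -0.15, G = matrix(0, 2, 2) + diag(1e-12, 2),
                     sigma2 = 100)
  hp <- spm_params(lmmT, gamma = 0, alpha = 0, xi = rep(0.08, 7))
  cfg <- sim_config(n_per_arm = 5000, mechanism = "mnar_spm",
                    mech_params = hp, lmm = lmmT, seed = 19)
  tr <- simulate_trial(cfg)
  lat <- tr$latent_dropout
  ## alpha = gamma = 0, constant baseline: truncated Exponential(0.08)
  obs <- lat[is.finite(lat)]
  Ftrunc <- function(t) pexp(t, 0.08) / pexp(36, 0.08)
  ks <- suppressWarnings(ks.test(obs, Ftrunc))
  expect_lt(unname(ks$statistic), 0.02)
  ## censoring fraction matches exp(-0.08 * 36)
  expect_lt(abs(mean(!is.finite(lat)) - exp(-0.08 * 36)),
            3 * sqrt(exp(-0.08 * 36) / length(lat)))
  ## hazard -> 0 keeps everyone to the end
  hp0 <- spm_params(lmmT, gamma = 0, alpha = 0, xi = rep(1e-10, 7))
  cfg0 <- sim_config(n_per_arm = 20, mechanism = "mnar_spm",
                     mech_params = hp0, lmm = lmmT, seed = 20)
  tr0 <- simulate_trial(cfg0)
  expect_true(all(tr0$dataset$dropout == 8L))
})

test_that("empirical cumulative incidence matches the model average", {
  lmmT <- lmm_params(60, 0.5, -0.15, G = matrix(c(300, -2, -2, 0.5), 2),
                     sigma2 = 100)
  hp <- spm_params(lmmT, gamma = 0.2, alpha = -0.01, xi = rep(0.1, 7))
  cfg <- sim_config(n_per_arm = 2000, mechanism = "mnar_spm",
                    mech_params = hp, lmm = lmmT, seed = 21)
  tr <- simulate_trial(cfg)
  tq <- 6
  model_ci <- mean(sapply(seq_along(tr$dataset$id), function(i) {
    1 - exp(-cumulative_hazard(hp, tr$random_effects[i, ],
                               tr$dataset$arm[i], tq))
  }))
  emp <- mean(tr$latent_dropout <= tq)
  expect_lt(abs(emp - model_ci), 3 * sqrt(model_ci * (1 - model_ci) / 4000))
})

test_that("pattern mechanism honours its proportions and shifts", {
  mp <- list(pi = c(1, 0, 0, 0), scheme = pattern_scheme(),
             shifts = matrix(0, 4, 3))
  cfg <- sim_config(n_per_arm = 20, mechanism = "pattern", mech_params = mp,
                    seed = 23)
  tr <- simulate_trial(cfg)
  expect_true(all(tr$pattern_labels == 1L))
  expect_true(all(tr$dataset$dropout <= 3L))
})

test_that("mechanism-inconsistent parameters are rejected", {
  expect_error(sim_config(mechanism = "mcar",
                          mech_params = dk_params(0, 0.1, 0)),
               "psi1")
  expect_error(sim_config(mechanism = "mar_dk",
                          mech_params = dk_params(0, 0.1, 0.2)),
               "psi2")
  expect_error(sim_config(mechanism = "mnar_spm",
                          mech_params = dk_params(0, 0, 0)),
               "spm_params")
  expect_error(sim_config(mechanism = "pattern",
                          mech_params = list(pi = c(0.5, 0.5))),
               "scheme")
})

test_that("truncation clips to the score range and flags the dataset", {
  cfg <- sim_config(n_per_arm = 50, mechanism = "mcar",
                    truncate_scores = TRUE, seed = 29)
  tr <- simulate_trial(cfg)
  sc <- tr$dataset$scores
  expect_true(all(sc[!is.na(sc)] >= 0 & sc[!is.na(sc)] <= 100))
  expect_true(attr(tr$dataset, "truncated"))
})

test_that("ground-truth sidecar round-trips through the writer", {
  cfg <- sim_config(n_per_arm = 6, mechanism = "mnar_spm", seed = 31)
  tr <- simulate_trial(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- write_sim_trial(tr, path)
  expect_true(file.exists(paths[1]) && file.exists(paths[2]))
  truth <- read.csv(paths[2])
  expect_equal(truth$b0, tr$random_effects[, 1])
  expect_equal(unname(as.matrix(truth[, grep("complete_", names(truth))])),
               unname(tr$complete_scores))
  back <- read_trial_csv(paths[1], cfg$schedule)
  expect_identical(unname(back$scores), unname(tr$dataset$scores))
})
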