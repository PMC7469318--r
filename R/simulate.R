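#' Configuration of a synthetic trial
#'
#' Describes the generative model of a two-arm longitudinal HRQoL trial:
#' random-intercept/random-slope Gaussian trajectories on the planned visit
#' schedule, and monotone dropout generated under one of several
#' mechanisms:
#' \describe{
#'   \item{`none`}{no dropout: everyone completes.}
#'   \item{`mcar`}{visit-by-visit logistic dropout with `psi1 = psi2 = 0`
#'     (missingness independent of the score).}
#'   \item{`mar_dk`}{logistic dropout on the last *observed* score
#'     (`psi2` forced to 0).}
#'   \item{`mnar_dk`}{logistic dropout on the last observed and the
#'     current unobserved score (informative).}
#'   \item{`mnar_spm`}{continuous dropout time from the proportional
#'     hazard with current-value association and piecewise-constant
#'     baseline.}
#'   \item{`pattern`}{pattern labels drawn from supplied proportions, with
#'     pattern-specific fixed-effect shifts and dropout uniform within the
#'     pattern's visit set.}
#' }
#' Defaults emulate the motivating oncology trial: 130 subjects per arm,
#' eight visits at months 0, 1.25, 3, 4, 6, 12, 24, 36, an intercept near
#' 60 points with a mild improvement in the control arm, and dropout
#' reaching most subjects by month 36.
#'
#' @param n_per_arm Subjects per arm (>= 1).
#' @param schedule A [visit_schedule()].
#' @param lmm True [lmm_params()].
#' @param mechanism One of the mechanisms above.
#' @param mech_params A [dk_params()] for the logistic mechanisms; an
#'   [spm_params()] for `mnar_spm` (its `lmm` part is replaced by the
#'   config's truth); for `pattern`, a list with `pi`, `scheme`
#'   ([pattern_scheme()]) and `shifts` (K x 3 matrix of fixed-effect
#'   shifts). `NULL` selects mechanism-specific defaults.
#' @param truncate_scores Clip scores to \[0, 100\] *after* dropout
#'   generation; off by default since the models assume unbounded Gaussian
#'   scores (an opt-in robustness stressor, flagged on the dataset).
#' @param seed Integer seed; the generator uses R's default Mersenne-
#'   Twister stream, so identical configs reproduce identical trials.
#' @return Object of class `sim_config`.
#' @examples
#' sim_config(n_per_arm = 50, mechanism = "mnar_dk", seed = 7)
#' @export
sim_config <- function(n_per_arm = 130,
                       schedule = visit_schedule(),
                       lmm = lmm_params(60, 0.5, -0.15,
                                        G = matrix(c(300, -2, -2, 0.5), 2),
                                        sigma2 = 100),
                       mechanism = c("mcar", "none", "mar_dk", "mnar_dk",
                                     "mnar_spm", "pattern"),
                       mech_params = NULL,
                       truncate_scores = FALSE,
                       seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_per_arm >= 1, inherits(schedule, "visit_schedule"),
            inherits(lmm, "lmm_params"))
  if (is.null(mech_params)) {
    mech_params <- switch(
      mechanism,
      none = NULL,
      mcar = dk_params(-0.55, 0, 0),
      mar_dk = dk_params(0.3, -0.015, 0),
      mnar_dk = dk_params(-0.808, -0.005, 0.005),
      mnar_spm = spm_params(lmm, gamma = -0.04, alpha = -0.015,
                            xi = rep(0.12, 7)),
      pattern = list(pi = c(0.35, 0.28, 0.23, 0.14),
                     scheme = pattern_scheme(J = schedule$J),
                     shifts = cbind(beta0 = c(0, 0, 0, 0),
                                    beta1 = c(-3, -1, -0.3, 0),
                                    beta2 = c(0, 0, 0, 0)))
    )
  }
  ## mechanism-consistent constraints
  if (mechanism %in% c("mcar", "mar_dk", "mnar_dk")) {
    if (!inherits(mech_params, "dk_params")) {
      stop("mech_params must be dk_params for mechanism ", mechanism,
           call. = FALSE)
    }
    if (mechanism == "mcar" && any(mech_params$psi[2:3] != 0)) {
      stop("mcar requires psi1 = psi2 = 0", call. = FALSE)
    }
    if (mechanism == "mar_dk" && mech_params$psi[3L] != 0) {
      stop("mar_dk requires psi2 = 0", call. = FALSE)
    }
  }
  if (mechanism == "mnar_spm") {
    if (!inherits(mech_params, "spm_params")) {
      stop("mech_params must be spm_params for mechanism mnar_spm",
           call. = FALSE)
    }
    mech_params$lmm <- lmm  # hazard part only; trajectory truth from config
  }
  if (mechanism == "pattern") {
    if (!is.list(mech_params) ||
        !all(c("pi", "scheme", "shifts") %in% names(mech_params))) {
      stop("pattern mechanism needs list(pi, scheme, shifts)", call. = FALSE)
    }
    K <- mech_params$scheme$K
    if (length(mech_params$pi) != K ||
        abs(sum(mech_params$pi) - 1) > 1e-8 || any(mech_params$pi < 0)) {
      stop("'pi' must be a length-K probability vector", call. = FALSE)
    }
    if (!all(dim(as.matrix(mech_params$shifts)) == c(K, 3L))) {
      stop("'shifts' must be a K x 3 matrix", call. = FALSE)
    }
  }
  structure(list(n_per_arm = as.integer(n_per_arm), schedule = schedule,
                 lmm = lmm, mechanism = mechanism, mech_params = mech_params,
                 truncate_scores = isTRUE(truncate_scores),
                 seed = as.integer(seed),
                 rng_kind = "Mersenne-Twister"),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trial config:", 2 * x$n_per_arm, "subjects,",
      x$schedule$J, "visits, mechanism =", x$mechanism,
      ", seed =", x$seed, "\n")
  invisible(x)
}

## complete trajectories, no dropout; assumes RNG state already set
sim_complete_ <- function(config) {
  n <- 2L * config$n_per_arm
  arm <- rep(0:1, each = config$n_per_arm)
  tt <- config$schedule$times
  J <- config$schedule$J
  b <- MASS::mvrnorm(n, mu = c(0, 0), Sigma = config$lmm$G)
  if (is.null(dim(b))) b <- matrix(b, 1L)
  be <- config$lmm$beta
  mean_fix <- outer(be[2L] + be[3L] * arm, tt) + be[1L]
  y <- mean_fix + b[, 1L] + outer(b[, 2L], tt) +
    matrix(stats::rnorm(n * J, sd = sqrt(config$lmm$sigma2)), n, J)
  list(arm = arm, y = y, b = b,
       id = sprintf("S%04d", seq_len(n)))
}

#' Simulate complete trajectories (no dropout)
#'
#' @param config A [sim_config()].
#' @return A `sim_trial` object whose dataset has no missing values;
#'   `complete_scores` and `random_effects` carry the ground truth.
#' @export
simulate_complete <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = config$rng_kind)
  cp <- sim_complete_(config)
  sim_trial_build(cp, D = rep(config$schedule$J, length(cp$arm)),
                  latent = NULL, config = config)
}

sim_trial_build <- function(cp, D, latent, config, extra = list()) {
  J <- config$schedule$J
  scores <- cp$y
  for (i in seq_along(D)) {
    if (D[i] < J) scores[i, (D[i] + 1L):J] <- NA_real_
  }
  truncated <- FALSE
  if (config$truncate_scores) {
    scores <- pmin(pmax(scores, 0), 100)
    truncated <- TRUE
  }
  ds <- trial_data(cp$id, cp$arm, scores, config$schedule)
  attr(ds, "truncated") <- if (truncated) TRUE else NULL
  structure(c(list(dataset = ds, complete_scores = cp$y,
                   random_effects = cp$b, latent_dropout = latent,
                   config = config), extra),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cat("Simulated trial (mechanism =", x$config$mechanism, ")\n")
  print(x$dataset)
  invisible(x)
}

#' Apply visit-by-visit logistic dropout
#'
#' Sequential discrete-time dropout: at each non-final visit j, a subject
#' still in the study drops (last available visit = j) with probability
#' `invlogit(psi0 + psi1 y_j + psi2 y_{j+1})` computed from its *complete*
#' scores (the current value is the score that would have been observed).
#' Survivors complete the study.
#'
#' @param trial A `sim_trial` with complete scores.
#' @param dk A [dk_params()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A new `sim_trial` with the masked observed view.
#' @export
apply_dk_dropout <- function(trial, dk, seed = NULL) {
  stopifnot(inherits(trial, "sim_trial"), inherits(dk, "dk_params"))
  if (!is.null(seed)) set.seed(seed, kind = trial$config$rng_kind)
  y <- trial$complete_scores
  n <- nrow(y); J <- ncol(y)
  D <- rep.int(J, n)
  alive <- rep.int(TRUE, n)
  for (j in seq_len(J - 1L)) {
    p <- dk_hazard(dk, y[, j], y[, j + 1L])
    drop_now <- alive & (stats::runif(n) < p)
    D[drop_now] <- j
    alive[drop_now] <- FALSE
  }
  cp <- list(arm = trial$dataset$arm, y = y, b = trial$random_effects,
             id = trial$dataset$id)
  sim_trial_build(cp, D, latent = NULL, config = trial$config)
}

#' Apply continuous-time hazard dropout
#'
#' Draws a latent continuous dropout time per subject by inverse-transform
#' sampling from the subject-specific cumulative hazard (piecewise-analytic
#' inversion of the closed form, censoring at the last scheduled visit);
#' the observed dropout index is the last scheduled visit strictly before
#' the latent time.
#'
#' @param trial A `sim_trial` with complete scores and random effects.
#' @param hazard_params An [spm_params()] (its LMM part should be the
#'   trajectory truth).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A new `sim_trial`; `latent_dropout` holds the continuous times
#'   (`Inf` when censored at the end of the schedule).
#' @export
apply_spm_dropout <- function(trial, hazard_params, seed = NULL) {
  stopifnot(inherits(trial, "sim_trial"), inherits(hazard_params, "spm_params"))
  if (!is.null(seed)) set.seed(seed, kind = trial$config$rng_kind)
  n <- nrow(trial$complete_scores)
  tt <- trial$config$schedule$times
  J <- length(tt)
  t_end <- tt[J]
  u <- stats::runif(n)
  latent <- numeric(n)
  D <- integer(n)
  for (i in seq_len(n)) {
    latent[i] <- invert_cumhaz(hazard_params, trial$random_effects[i, ],
                               trial$dataset$arm[i], -log(u[i]), t_end)
    D[i] <- if (latent[i] >= t_end) J else max(1L, sum(tt < latent[i]))
  }
  cp <- list(arm = trial$dataset$arm, y = trial$complete_scores,
             b = trial$random_effects, id = trial$dataset$id)
  sim_trial_build(cp, D, latent = latent, config = trial$config)
}

## solve Lambda(t) = target on [0, t_end]; Inf-like t_end when not reached
invert_cumhaz <- function(params, b, arm, target, t_end) {
  be <- params$lmm$beta
  a0 <- be[1L] + b[1L]
  s <- be[2L] + be[3L] * arm + b[2L]
  al <- params$alpha
  starts <- c(0, params$knots); ends <- c(params$knots, Inf)
  acc <- 0
  for (q in seq_along(params$xi)) {
    l <- starts[q]; u <- min(ends[q], t_end)
    if (u <= l) break
    dl <- u - l
    A <- params$xi[q] * exp(params$gamma * arm + al * (a0 + s * l))
    seg <- A * dl * relexpm1(al * s * dl)
    if (acc + seg >= target) {
      rem <- target - acc
      z <- al * s
      if (abs(z) < 1e-10) return(l + rem / A)
      arg <- rem * z / A
      if (arg <= -1) return(l + dl)  # numerically at the segment end
      return(l + log1p(arg) / z)
    }
    acc <- acc + seg
    if (u >= t_end) break
  }
  Inf
}

#' Simulate a trial under a configured dropout mechanism
#'
#' Seeds the RNG once from the config, draws complete trajectories, then
#' applies the configured dropout mechanism; the observed dataset is
#' always a deterministic mask of the complete scores given the dropout
#' index.
#'
#' @param config A [sim_config()].
#' @return A `sim_trial`: `dataset` (the observed [trial_data()]),
#'   `complete_scores`, `random_effects`, `latent_dropout` (continuous
#'   mechanism only), `config`, and for the pattern mechanism
#'   `pattern_labels`.
#' @examples
#' tr <- simulate_trial(sim_config(n_per_arm = 40, mechanism = "mnar_dk",
#'                                 seed = 42))
#' summarize_missingness(tr$dataset)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed, kind = config$rng_kind)
  if (config$mechanism == "pattern") {
    mp <- config$mech_params
    n <- 2L * config$n_per_arm
    K <- mp$scheme$K
    lab <- sample.int(K, n, replace = TRUE, prob = mp$pi)
    ## pattern-specific fixed effects; then draw D within the pattern's set
    cp0 <- sim_complete_(config)  # draws b and residuals at base truth
    sh <- as.matrix(mp$shifts)
    tt <- config$schedule$times
    adj <- sh[lab, 1L] + outer(sh[lab, 2L], tt) +
      sh[lab, 3L] * cp0$arm * matrix(tt, n, length(tt), byrow = TRUE)
    cp0$y <- cp0$y + adj
    D <- vapply(lab, function(k) {
      set <- mp$scheme$sets[[k]]
      set[sample.int(length(set), 1L)]
    }, integer(1))
    return(sim_trial_build(cp0, D, latent = NULL, config = config,
                           extra = list(pattern_labels = lab)))
  }
  base <- sim_trial_build(sim_complete_(config),
                          D = rep(config$schedule$J, 2L * config$n_per_arm),
                          latent = NULL, config = config)
  switch(config$mechanism,
         none = base,
         mcar = ,
         mar_dk = ,
         mnar_dk = apply_dk_dropout(base, config$mech_params),
         mnar_spm = apply_spm_dropout(base, config$mech_params))
}

#' Write a simulated trial with its ground-truth sidecar
#'
#' Writes the observed dataset in the long CSV format of
#' [write_trial_csv()] plus a sidecar CSV holding the complete scores,
#' random effects and latent dropout times, for provenance and
#' parameter-recovery work.
#'
#' @param trial A `sim_trial`.
#' @param path Observed-data CSV path; the sidecar gets suffix
#'   `_truth.csv`.
#' @return Invisibly, the two paths.
#' @export
write_sim_trial <- function(trial, path) {
  stopifnot(inherits(trial, "sim_trial"))
  write_trial_csv(trial$dataset, path)
  J <- ncol(trial$complete_scores)
  truth <- data.frame(
    subject_id = trial$dataset$id,
    arm = trial$dataset$arm,
    b0 = trial$random_effects[, 1L],
    b1 = trial$random_effects[, 2L],
    latent_dropout = if (is.null(trial$latent_dropout)) NA_real_
                     else trial$latent_dropout
  )
  truth <- cbind(truth, as.data.frame(trial$complete_scores))
  names(truth)[5L + seq_len(J)] <- paste0("complete_", trial$dataset$schedule$labels)
  tp <- sub("\\.csv$", "_truth.csv", path)
  if (identical(tp, path)) tp <- paste0(path, "_truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE)
  invisible(c(path, tp))
}
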