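#' Parameters of the random-coefficients linear mixed model
#'
#' The score of subject i at planned visit time t is modelled as
#' \deqn{Y_i(t) = \beta_0 + \beta_1 t + \beta_2 \,\mathrm{arm}_i\, t
#'   + b_{0i} + b_{1i} t + \varepsilon_i(t)}
#' with \eqn{(b_{0i}, b_{1i}) \sim N(0, G)} and
#' \eqn{\varepsilon \sim N(0, \sigma^2)}. `beta1` is the slope in the
#' control arm (points/month) and `beta2` the arm-by-time interaction, so
#' `beta1 + beta2` is the experimental-arm slope. Both arms share the
#' intercept: randomization justifies a common baseline mean, and arm enters
#' the mean only through the interaction.
#'
#' @param beta0,beta1,beta2 Fixed effects: intercept (points), control-arm
#'   slope and arm-by-time interaction (points/month).
#' @param G 2x2 random-effects covariance (intercept variance in points^2,
#'   slope variance in (points/month)^2); must be symmetric positive
#'   semi-definite.
#' @param sigma2 Residual variance (points^2), > 0.
#' @return An object of class `lmm_params`.
#' @examples
#' lmm_params(60, 0.5, -0.15, G = diag(c(300, 0.5)), sigma2 = 100)
#' @export
lmm_params <- function(beta0, beta1, beta2, G, sigma2) {
  G <- as.matrix(G)
  stopifnot(identical(dim(G), c(2L, 2L)))
  if (max(abs(G - t(G))) > 1e-8) stop("'G' must be symmetric", call. = FALSE)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("'G' must be positive semi-definite", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be > 0", call. = FALSE)
  structure(list(beta = c(beta0 = unname(beta0), beta1 = unname(beta1),
                          beta2 = unname(beta2)),
                 G = (G + t(G)) / 2, sigma2 = sigma2),
            class = "lmm_params")
}

#' @export
print.lmm_params <- function(x, ...) {
  cat("LMM parameters\n  fixed effects:",
      sprintf("beta0 = %.4g, beta1 = %.4g, beta2 = %.4g",
              x$beta[1], x$beta[2], x$beta[3]), "\n")
  cat("  G (random intercept/slope covariance):\n")
  print(unname(x$G))
  cat("  sigma2 =", format(x$sigma2), "\n")
  invisible(x)
}

#' Marginal mean and covariance of the score vector
#'
#' For a subject in the given arm observed at `times`, returns the implied
#' marginal moments: mean \eqn{\mu_j = \beta_0 + (\beta_1 + \beta_2
#' \mathrm{arm}) t_j} and covariance \eqn{V = Z G Z' + \sigma^2 I} with
#' \eqn{Z = [1, t_j]}.
#'
#' @param params An [lmm_params()] object.
#' @param arm 0 or 1.
#' @param times Numeric vector of visit times (months), non-empty.
#' @return List with `mean` (vector) and `cov` (matrix).
#' @export
marginal_moments <- function(params, arm, times) {
  stopifnot(inherits(params, "lmm_params"), length(times) >= 1L)
  b <- params$beta
  Z <- cbind(1, times)
  list(mean = unname(b[1L] + (b[2L] + b[3L] * arm) * times),
       cov = Z %*% params$G %*% t(Z) + diag(params$sigma2, length(times)))
}

#' Predicted mean score trajectory
#'
#' The fixed-effects mean of the model at the given times, for one arm:
#' the curve a trajectory plot displays. The arm difference at time t is
#' `beta2 * t` exactly.
#'
#' @inheritParams marginal_moments
#' @return Numeric vector of mean scores.
#' @export
predict_mean <- function(params, arm, times) {
  marginal_moments(params, arm, times)$mean
}

## dataset -> per-subject lists for the core machinery (observed visits only)
lmm_lists <- function(dataset, design = c("arm_by_time")) {
  n <- n_subjects(dataset)
  times <- dataset$schedule$times
  tl <- vector("list", n); Xl <- vector("list", n); yl <- vector("list", n)
  obsl <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- which(!is.na(dataset$scores[i, ]))
    tt <- times[obs]
    tl[[i]] <- tt
    Xl[[i]] <- cbind(1, tt, dataset$arm[i] * tt)
    yl[[i]] <- dataset$scores[i, obs]
    obsl[[i]] <- obs
  }
  list(times = tl, X = Xl, y = yl, obs = obsl)
}

#' Observed-data log-likelihood of the LMM
#'
#' Evaluates the marginal (observed-data) log-likelihood of a trial dataset
#' at given parameter values: each subject contributes the multivariate
#' normal log-density of its available scores. The REML variant is the
#' restricted log-likelihood at those variance components (it does not
#' depend on the fixed effects, which are profiled out by generalized least
#' squares).
#'
#' @param params An [lmm_params()] object.
#' @param dataset A [trial_data()] object.
#' @param method `"ML"` or `"REML"`.
#' @return A finite scalar.
#' @export
lmm_loglik <- function(params, dataset, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "lmm_params"), inherits(dataset, "trial_data"))
  L <- lmm_lists(dataset)
  gr <- lmm_groups(L$times, L$X, L$y)
  theta <- vc_to_theta(params$G, params$sigma2)
  lmm_loglik_at(unname(params$beta), theta, gr, method)
}

#' Fit the linear mixed model
#'
#' Maximum (or restricted maximum) likelihood fit of the
#' random-intercept/random-slope model to the available scores. Valid for
#' inference when dropout is (at most) missing-at-random; it is also the
#' longitudinal sub-model the selection, pattern-mixture and
#' shared-parameter models build on. The variance components are optimized
#' on an unconstrained log-Cholesky scale (positive definiteness by
#' construction) with the fixed effects profiled out by generalized least
#' squares; Wald inference uses the normal reference distribution.
#'
#' @param dataset A [trial_data()] object with at least two subjects and two
#'   distinct observation times.
#' @param method `"REML"` (default for the standalone model) or `"ML"` (used
#'   inside joint likelihoods).
#' @return An object of class `c("qol_lmm", "qol_fit")` with components
#'   `params` ([lmm_params()]), `se` and `vcov_fixed` for the fixed effects,
#'   `loglik`, `method`, `converged`.
#' @examples
#' tr <- simulate_trial(sim_config(n_per_arm = 60, seed = 1))
#' fit <- fit_lmm(tr$dataset)
#' coef(fit)
#' @export
fit_lmm <- function(dataset, method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "trial_data"))
  if (n_subjects(dataset) < 2L) {
    stop("need at least two subjects", call. = FALSE)
  }
  L <- lmm_lists(dataset)
  if (length(unique(unlist(L$times))) < 2L) {
    stop("degenerate design: need at least two distinct observation times",
         call. = FALSE)
  }
  core <- lmm_core_fit(L$times, L$X, L$y, method = method)
  params <- lmm_params(core$beta[1L], core$beta[2L], core$beta[3L],
                       core$G, core$sigma2)
  structure(list(params = params,
                 se = stats::setNames(core$se, names(params$beta)),
                 vcov_fixed = core$vcov_fixed,
                 loglik = core$loglik, method = method,
                 converged = core$converged, theta = core$theta,
                 n = n_subjects(dataset), dataset = dataset,
                 core = core, lists = L),
            class = c("qol_lmm", "qol_fit"))
}

#' @export
coef.qol_lmm <- function(object, ...) object$params$beta

#' @export
logLik.qol_lmm <- function(object, ...) {
  structure(object$loglik, df = 7L, class = "logLik")
}

#' @export
vcov.qol_lmm <- function(object, ...) object$vcov_fixed

#' @rdname fit_lmm
#' @param object,x A fitted `qol_lmm` object.
#' @param arm Arm indicator for prediction (0/1).
#' @param times Times at which to predict; defaults to the visit schedule.
#' @param ... Unused.
#' @export
predict.qol_lmm <- function(object, arm = 0, times = NULL, ...) {
  if (is.null(times)) times <- object$dataset$schedule$times
  predict_mean(object$params, arm, times)
}

#' @export
print.qol_lmm <- function(x, ...) {
  cat("Linear mixed model (", x$method, "), n = ", x$n,
      ", logLik = ", format(x$loglik), "\n", sep = "")
  print(wald_table(coef(x), x$se))
  cat("sigma2 =", format(x$params$sigma2),
      "; G diag =", format(diag(x$params$G)), "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.qol_lmm <- function(object, ...) {
  out <- list(fixed = wald_table(coef(object), object$se),
              G = object$params$G, sigma2 = object$params$sigma2,
              loglik = object$loglik, method = object$method,
              converged = object$converged)
  class(out) <- "summary.qol_lmm"
  out
}

#' @export
print.summary.qol_lmm <- function(x, ...) {
  cat("Random-coefficients LMM (", x$method, ")\n\nFixed effects:\n", sep = "")
  print(x$fixed)
  cat("\nRandom effects covariance G:\n"); print(unname(x$G))
  cat("Residual variance:", format(x$sigma2), "\n")
  cat("Log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
simulate.qol_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ds <- object$dataset
  replicate(nsim, {
    cfg <- sim_config(n_per_arm = max(table(factor(ds$arm, 0:1))),
                      schedule = ds$schedule, lmm = object$params,
                      mechanism = "none", seed = sample.int(2^31 - 1, 1))
    simulate_trial(cfg)$dataset
  }, simplify = FALSE)
}

## Wald table helper shared by all fits
wald_table <- function(est, se, conf = 0.95) {
  z <- est / se
  q <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(estimate = est, se = se,
             ci_lo = est - q * se, ci_hi = est + q * se,
             z = z, p = 2 * stats::pnorm(-abs(z)),
             row.names = names(est))
}
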