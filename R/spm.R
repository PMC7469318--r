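#' Parameters of the shared-parameter joint model
#'
#' Joint model for the score trajectory and the time to dropout. The
#' longitudinal sub-model is the random-coefficients LMM; the dropout
#' sub-model is a proportional-hazards model on continuous time,
#' \deqn{\lambda_i(t) = \lambda_0(t) \exp\{\gamma\,\mathrm{arm}_i +
#'   \alpha\, Y_i^*(t)\}}
#' where \eqn{Y_i^*(t) = \beta_0 + b_{0i} + (\beta_1 + \beta_2\mathrm{arm}_i
#' + b_{1i}) t} is the current *true* (error-free) score and
#' \eqn{\lambda_0} is piecewise constant with levels `xi` between `knots`
#' (intervals left-closed, right-open; the last is open-ended). The two
#' processes are linked only through the shared random effects, so they are
#' conditionally independent given \eqn{b_i}.
#'
#' @param lmm An [lmm_params()] object (longitudinal sub-model truth).
#' @param gamma Arm effect on the log-hazard of dropout (dimensionless).
#' @param alpha Association between current true score and log-hazard
#'   (per point).
#' @param xi Positive baseline-hazard levels (events/month), one per
#'   interval; `length(xi) == length(knots) + 1`.
#' @param knots Internal knot times in months; default the six knots at the
#'   interior scheduled visits, giving seven intervals.
#' @return An object of class `spm_params`.
#' @export
spm_params <- function(lmm, gamma = 0, alpha = 0,
                       xi = rep(0.1, 7),
                       knots = c(1.25, 3, 4, 6, 12, 24)) {
  stopifnot(inherits(lmm, "lmm_params"))
  knots <- as.numeric(knots)
  if (is.unsorted(knots, strictly = TRUE) || any(knots <= 0)) {
    stop("'knots' must be positive and strictly increasing", call. = FALSE)
  }
  if (length(xi) != length(knots) + 1L) {
    stop("need length(xi) == length(knots) + 1 baseline-hazard levels",
         call. = FALSE)
  }
  if (any(!is.finite(xi)) || any(xi <= 0)) {
    stop("'xi' must be positive", call. = FALSE)
  }
  structure(list(lmm = lmm, gamma = gamma, alpha = alpha,
                 xi = as.numeric(xi), knots = knots),
            class = "spm_params")
}

#' @export
print.spm_params <- function(x, ...) {
  cat("Shared-parameter model parameters\n")
  print(x$lmm)
  cat(sprintf("  gamma = %.4g, alpha = %.4g\n", x$gamma, x$alpha))
  cat("  baseline hazard levels:", format(x$xi, digits = 4), "\n")
  cat("  knots (months):", x$knots, "\n")
  invisible(x)
}

## interval containing t (left-closed, right-open)
hazard_interval <- function(t, knots) findInterval(t, knots) + 1L

## expm1(z)/z with the z -> 0 limit
relexpm1 <- function(z) {
  out <- ifelse(abs(z) < 1e-8, 1 + z / 2, expm1(z) / z)
  out
}

#' Current true score value
#'
#' The error-free trajectory value shared with the dropout hazard:
#' `beta0 + b0 + (beta1 + beta2*arm + b1) * t`.
#'
#' @param lmm An [lmm_params()] object.
#' @param b Length-2 random-effect vector `(b0, b1)`.
#' @param arm 0 or 1.
#' @param t Time(s) in months.
#' @return Score value(s) in points.
#' @export
current_value <- function(lmm, b, arm, t) {
  stopifnot(inherits(lmm, "lmm_params"), length(b) == 2L)
  be <- unname(lmm$beta)
  be[1L] + b[1L] + (be[2L] + be[3L] * arm + b[2L]) * t
}

#' Dropout hazard and cumulative hazard of the joint model
#'
#' `spm_hazard()` evaluates \eqn{\xi_{q(t)} \exp\{\gamma\,\mathrm{arm} +
#' \alpha Y^*(t)\}}. Because \eqn{Y^*} is linear in t, the integral over
#' each baseline interval is analytic, and `cumulative_hazard()` uses that
#' closed form (with the usual `expm1` limit when `alpha * slope` vanishes).
#'
#' @param params An [spm_params()] object.
#' @param b Length-2 random-effect vector.
#' @param arm 0 or 1.
#' @param t Time(s) in months, >= 0.
#' @return Hazard in events/month, or dimensionless cumulative hazard.
#' @export
spm_hazard <- function(params, b, arm, t) {
  stopifnot(inherits(params, "spm_params"))
  q <- hazard_interval(t, params$knots)
  params$xi[q] * exp(params$gamma * arm +
                     params$alpha * current_value(params$lmm, b, arm, t))
}

#' @rdname spm_hazard
#' @export
cumulative_hazard <- function(params, b, arm, t) {
  stopifnot(inherits(params, "spm_params"))
  be <- params$lmm$beta
  a0 <- be[1L] + b[1L]
  s <- be[2L] + be[3L] * arm + b[2L]
  starts <- c(0, params$knots)
  ends <- c(params$knots, Inf)
  vapply(t, function(tt) {
    stopifnot(tt >= 0)
    tot <- 0
    for (q in seq_along(params$xi)) {
      if (starts[q] >= tt) break
      u <- min(ends[q], tt)
      dl <- u - starts[q]
      z <- params$alpha * s * dl
      tot <- tot + params$xi[q] *
        exp(params$gamma * arm + params$alpha * (a0 + s * starts[q])) *
        dl * relexpm1(z)
    }
    unname(tot)
  }, numeric(1))
}

#' Hazard ratio for a score change
#'
#' Under the current-value association, a change of `delta` points in the
#' true score multiplies the dropout hazard by `exp(alpha * delta)`. For
#' instance `alpha = -0.015`, `delta = -10` (a 10-point deterioration)
#' gives a hazard ratio of about 1.16. Confidence limits are obtained by
#' applying the same transform to the limits of `alpha` (and sorting, since
#' the transform is decreasing for negative `delta`).
#'
#' @param alpha Association parameter (per point).
#' @param delta Score change in points.
#' @param ci Optional length-2 confidence limits for `alpha`.
#' @return The hazard ratio, with attribute `ci` when limits are supplied.
#' @examples
#' dropout_hazard_ratio(-0.015, -10)                    # 1.1618
#' dropout_hazard_ratio(-0.015, -10, ci = c(-0.03, 0))  # CI [1, 1.3499]
#' @export
dropout_hazard_ratio <- function(alpha, delta, ci = NULL) {
  hr <- exp(alpha * delta)
  if (!is.null(ci)) {
    stopifnot(length(ci) == 2L)
    attr(hr, "ci") <- sort(exp(ci * delta))
  }
  hr
}

#' Dropout times implied by a trial dataset
#'
#' The dropout variable of the joint model: `T` is the time of the last
#' available visit and `event = 1` when the subject dropped out before the
#' final visit (`event = 0` marks administrative censoring at the last
#' scheduled visit).
#'
#' @param dataset A [trial_data()] object.
#' @return Data frame with columns `id`, `arm`, `time`, `event`.
#' @export
derive_dropout_times <- function(dataset) {
  stopifnot(inherits(dataset, "trial_data"))
  J <- dataset$schedule$J
  data.frame(id = dataset$id, arm = dataset$arm,
             time = dataset$schedule$times[dataset$dropout],
             event = as.integer(dataset$dropout < J))
}

## ---- quadrature ------------------------------------------------------

## 2-D tensor Gauss-Hermite rule (physicists' weight exp(-|x|^2))
gh_rule2 <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  K <- nodes^2
  i1 <- rep(seq_len(nodes), each = nodes)
  i2 <- rep(seq_len(nodes), times = nodes)
  list(x1 = gh$x[i1], x2 = gh$x[i2],
       logw = log(gh$w[i1]) + log(gh$w[i2]),
       xsq = gh$x[i1]^2 + gh$x[i2]^2, K = K)
}

## Pseudo-adaptive centering: per-subject empirical-Bayes modes and scaled
## Cholesky factors of the posterior covariance, from an LMM fit (either a
## preliminary fit, fixed during joint optimization, or the evaluation
## parameters themselves).
spm_centering <- function(lmm_par, dataset) {
  L <- lmm_lists(dataset)
  fitlike <- list(beta = unname(lmm_par$beta), G = lmm_par$G,
                  sigma2 = lmm_par$sigma2)
  eb <- lmm_eb_modes(fitlike, L$times, L$X, L$y)
  n <- length(L$y)
  B <- matrix(0, n, 3L)  # B11, B21, B22 of lower Cholesky
  for (i in seq_len(n)) {
    Bl <- t(chol(eb$covs[[i]] + diag(1e-12, 2L)))
    B[i, ] <- c(Bl[1L, 1L], Bl[2L, 1L], Bl[2L, 2L])
  }
  list(modes = eb$modes, B = B, logdetB = log(B[, 1L] * B[, 3L]))
}

## Precompute everything about the data that does not change across
## likelihood evaluations. `dropout` overrides the default visit-grid
## dropout times (e.g. with exact latent times from a simulation).
spm_prepare <- function(dataset, dropout = NULL) {
  L <- lmm_lists(dataset)
  n <- length(L$y)
  st <- t(vapply(seq_len(n), function(i) {
    tt <- L$times[[i]]; y <- L$y[[i]]
    c(d = length(y), Sy = sum(y), Sty = sum(tt * y), Syy = sum(y^2),
      St = sum(tt), Stt = sum(tt^2))
  }, numeric(6)))
  dt <- if (is.null(dropout)) derive_dropout_times(dataset) else dropout
  if (nrow(dt) != n || !all(c("time", "event") %in% names(dt))) {
    stop("'dropout' must have one row per subject with columns time, event",
         call. = FALSE)
  }
  list(lists = L, stats = st, arm = dataset$arm,
       T = dt$time, event = dt$event, n = n,
       schedule = dataset$schedule)
}

#' Exact dropout times of a simulated trial
#'
#' For a trial simulated under the continuous-time hazard mechanism this
#' returns the latent dropout times (censored at the end of the schedule),
#' the event-time table a self-consistent joint-model fit should use. For
#' real data only the visit-grid convention of [derive_dropout_times()] is
#' available.
#'
#' @param trial A `sim_trial` with `latent_dropout` times.
#' @return Data frame with columns `time` and `event`.
#' @export
sim_dropout_times <- function(trial) {
  stopifnot(inherits(trial, "sim_trial"))
  if (is.null(trial$latent_dropout)) {
    stop("trial has no latent dropout times (mechanism was not mnar_spm)",
         call. = FALSE)
  }
  t_end <- max(trial$config$schedule$times)
  data.frame(time = pmin(trial$latent_dropout, t_end),
             event = as.integer(trial$latent_dropout < t_end))
}

## exposure segments (subject, interval, l, u) up to each subject's T,
## in subject order (consumed as CSR by the compiled core)
spm_exposure <- function(Tvec, knots) {
  starts <- c(0, knots); ends <- c(knots, Inf)
  rows <- lapply(seq_along(Tvec), function(i) {
    qmax <- hazard_interval(Tvec[i], knots)
    q <- seq_len(qmax)
    u <- pmin(ends[q], Tvec[i])
    keep <- u > starts[q]
    if (!any(keep)) return(NULL)
    cbind(i = i, q = q[keep], l = starts[q][keep], u = u[keep])
  })
  ex <- do.call(rbind, rows)
  if (is.null(ex)) {
    ex <- matrix(numeric(0), 0L, 4L,
                 dimnames = list(NULL, c("i", "q", "l", "u")))
  }
  ## 0-based row offsets per subject
  cnt <- tabulate(ex[, "i"], nbins = length(Tvec))
  attr(ex, "ptr") <- c(0L, cumsum(cnt))
  ex
}

## Core evaluation: thin wrapper over the compiled pseudo-adaptive
## quadrature loop (see src/loglik.cpp).
spm_loglik_core <- function(beta, G, sigma2, gamma, alpha, xi, knots,
                            pre, cen, gh) {
  ex <- pre$exposure
  spm_loglik_cpp(pre$stats, pre$arm, pre$T, as.integer(pre$event),
                 hazard_interval(pre$T, knots),
                 attr(ex, "ptr"), as.integer(ex[, "q"]),
                 ex[, "l"], ex[, "u"],
                 cen$modes, cen$B, cen$logdetB,
                 gh$x1, gh$x2, gh$logw, gh$xsq,
                 beta, G, sigma2, gamma, alpha, xi)
}

#' Log-likelihood of the shared-parameter model
#'
#' Each subject contributes the log of a two-dimensional integral over the
#' random effects of (longitudinal normal density) x (survival factor
#' `hazard^event * exp(-cumulative hazard)`) x (bivariate normal prior).
#' The integral is evaluated by pseudo-adaptive Gauss-Hermite quadrature:
#' nodes are centered and scaled at each subject's empirical-Bayes mode and
#' posterior curvature from an LMM fit, by default computed from the
#' longitudinal parameters being evaluated.
#'
#' @param params An [spm_params()] object.
#' @param dataset A [trial_data()] object.
#' @param nodes Gauss-Hermite nodes per dimension (>= 3); default 9.
#' @param centering Optional centering object from a preliminary fit (used
#'   internally by [fit_spm()]); by default derived from `params$lmm`.
#' @param dropout Optional dropout-time table (columns `time`, `event`, one
#'   row per subject); default the visit-grid times of
#'   [derive_dropout_times()].
#' @return Scalar log-likelihood.
#' @export
spm_loglik <- function(params, dataset, nodes = 9, centering = NULL,
                       dropout = NULL) {
  stopifnot(inherits(params, "spm_params"), inherits(dataset, "trial_data"),
            nodes >= 3)
  pre <- spm_prepare(dataset, dropout)
  pre$exposure <- spm_exposure(pre$T, params$knots)
  if (is.null(centering)) centering <- spm_centering(params$lmm, dataset)
  gh <- gh_rule2(nodes)
  spm_loglik_core(unname(params$lmm$beta), params$lmm$G, params$lmm$sigma2,
                  params$gamma, params$alpha, params$xi, params$knots,
                  pre, centering, gh)
}

## decoupled piecewise-exponential fit (alpha = 0) used for initialization
fit_pwexp <- function(Tvec, event, arm, knots) {
  Q <- length(knots) + 1L
  ex <- spm_exposure(Tvec, knots)
  qT <- hazard_interval(Tvec, knots)
  ## aggregated events and exposures by (interval, arm)
  ev <- matrix(0, Q, 2L); Ez <- matrix(0, Q, 2L)
  for (a in 0:1) {
    sel <- arm == a
    ev[, a + 1L] <- tabulate(qT[sel][event[sel] == 1L], nbins = Q)
    if (!is.null(ex)) {
      exa <- ex[sel[ex[, "i"]], , drop = FALSE]
      if (nrow(exa)) {
        Ez[, a + 1L] <- vapply(seq_len(Q), function(q) {
          sum((exa[, "u"] - exa[, "l"])[exa[, "q"] == q])
        }, numeric(1))
      }
    }
  }
  nll <- function(par) {
    lxi <- par[seq_len(Q)]; gam <- par[Q + 1L]
    if (any(!is.finite(lxi))) return(1e10)
    ll <- sum(ev[, 1L] * lxi) + sum(ev[, 2L] * (lxi + gam)) -
      sum(exp(lxi) * Ez[, 1L]) - sum(exp(lxi + gam) * Ez[, 2L])
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  tot_ev <- sum(ev); tot_ex <- sum(Ez)
  l0 <- log(max(tot_ev, 0.5) / max(tot_ex, 1e-8))
  opt <- stats::nlminb(c(rep(l0, Q), 0), nll,
                       lower = c(rep(-20, Q), -20),
                       upper = c(rep(5, Q), 20))
  list(log_xi = opt$par[seq_len(Q)], gamma = opt$par[Q + 1L],
       loglik = -opt$objective)
}

#' Fit the shared-parameter joint model
#'
#' Maximizes the joint likelihood over the LMM parameters, the arm effect
#' `gamma`, the association `alpha` and the log baseline-hazard levels.
#' Initialization decouples the two processes: a REML LMM for the
#' longitudinal part (which also provides the empirical-Bayes centering of
#' the quadrature, held fixed during the joint optimization) and a
#' piecewise-exponential fit with `alpha = 0` for the dropout part.
#' Standard errors come from the numerically differentiated observed
#' information; if that matrix cannot be inverted the fit is returned with
#' `hessian_ok = FALSE` and a warning rather than an error.
#'
#' @param dataset A [trial_data()] object; needs at least one dropout event
#'   (with none, the survival part is degenerate and the fit reduces to the
#'   LMM, with a warning).
#' @param knots Internal baseline-hazard knots (months).
#' @param nodes Gauss-Hermite nodes per dimension; default 9.
#' @param se Compute standard errors (numerical Hessian); default TRUE.
#' @param dropout Optional dropout-time table (columns `time`, `event`);
#'   default the trial-style visit-grid convention of
#'   [derive_dropout_times()]. Supply [sim_dropout_times()] output to fit
#'   simulated trials with their exact latent times (the visit-grid
#'   convention coarsens event times to the last attended visit, which
#'   biases the hazard scale when intervals are wide).
#' @param control Passed to [stats::optim()] (`L-BFGS-B`).
#' @return Object of class `c("qol_spm", "qol_fit")`: `params`
#'   ([spm_params()]), `se` (fixed effects, gamma, alpha), `xi_ci`
#'   (log-scale Wald intervals for the hazard levels), `loglik`,
#'   `converged`, `hessian_ok`, `nodes`.
#' @export
fit_spm <- function(dataset, knots = c(1.25, 3, 4, 6, 12, 24), nodes = 9,
                    se = TRUE, dropout = NULL, control = list()) {
  stopifnot(inherits(dataset, "trial_data"))
  Q <- length(knots) + 1L
  pre <- spm_prepare(dataset, dropout)
  pre$exposure <- spm_exposure(pre$T, knots)
  gh <- gh_rule2(nodes)
  prelim <- fit_lmm(dataset, method = "REML")
  cen <- spm_centering(prelim$params, dataset)
  if (sum(pre$event) == 0L) {
    warning("no dropout events: survival sub-model degenerate, ",
            "returning the LMM fit for the longitudinal part")
    ml <- fit_lmm(dataset, method = "ML")
    params <- spm_params(ml$params, gamma = 0, alpha = 0,
                         xi = rep(1e-8, Q), knots = knots)
    return(structure(list(params = params, se = c(ml$se, gamma = NA,
                                                  alpha = NA),
                          vcov = NULL, xi_ci = NULL, loglik = ml$loglik,
                          converged = ml$converged, hessian_ok = FALSE,
                          nodes = nodes, n = pre$n, n_events = 0L,
                          dataset = dataset, degenerate = TRUE),
                     class = c("qol_spm", "qol_fit")))
  }
  pw <- fit_pwexp(pre$T, pre$event, pre$arm, knots)
  start <- c(unname(prelim$params$beta),
             vc_to_theta(prelim$params$G, prelim$params$sigma2),
             pw$gamma, 0, pw$log_xi)
  unpack <- function(par) {
    vc <- theta_to_vc(par[4:7])
    list(beta = par[1:3], G = vc$G, sigma2 = vc$sigma2,
         gamma = par[8L], alpha = par[9L], xi = exp(par[9L + seq_len(Q)]))
  }
  ex <- pre$exposure
  qTv <- hazard_interval(pre$T, knots)
  cache <- new.env(parent = emptyenv())
  evalfg <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(invisible())
    res <- spm_loglik_grad_cpp(pre$stats, pre$arm, pre$T,
                               as.integer(pre$event), qTv,
                               attr(ex, "ptr"), as.integer(ex[, "q"]),
                               ex[, "l"], ex[, "u"],
                               cen$modes, cen$B, cen$logdetB,
                               gh$x1, gh$x2, gh$logw, gh$xsq,
                               par[1:3], par[4:7], par[8L], par[9L],
                               par[9L + seq_len(Q)])
    cache$par <- par; cache$val <- res$value; cache$grad <- res$gradient
    invisible()
  }
  nll <- function(par) {
    evalfg(par)
    if (!is.finite(cache$val)) return(1e10)
    -cache$val
  }
  ngr <- function(par) {
    evalfg(par)
    g <- cache$grad
    if (!is.finite(cache$val) || any(!is.finite(g))) return(numeric(length(par)))
    -drop(g)
  }
  lo <- c(rep(-1e4, 3), rep(-15, 3), -15, -20, -20, rep(-20, Q))
  hi <- c(rep(1e4, 3), rep(15, 3), 15, 20, 20, rep(5, Q))
  pscale <- c(10, 1, 1, 1, 1, 1, 1, 0.5, 0.01, rep(1, Q))
  ctl <- utils::modifyList(list(parscale = pscale, maxit = 400L,
                                factr = 1e7), control)
  opt <- stats::optim(start, nll, gr = ngr, method = "L-BFGS-B",
                      lower = lo, upper = hi, control = ctl)
  opt$objective <- opt$value
  converged <- opt$convergence == 0L && opt$objective < 1e9
  p <- unpack(opt$par)
  params <- spm_params(lmm_params(p$beta[1L], p$beta[2L], p$beta[3L],
                                  p$G, p$sigma2),
                       gamma = p$gamma, alpha = p$alpha, xi = p$xi,
                       knots = knots)
  se_vec <- rep(NA_real_, 5L)
  names(se_vec) <- c("beta0", "beta1", "beta2", "gamma", "alpha")
  vcov_par <- NULL; xi_ci <- NULL; hessian_ok <- FALSE
  if (se) {
    H <- tryCatch(hess_from_grad(ngr, opt$par), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_par <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_par) && all(diag(vcov_par)[c(1:3, 8:9)] > 0)) {
        hessian_ok <- TRUE
        se_vec[] <- sqrt(diag(vcov_par)[c(1:3, 8:9)])
        se_lxi <- sqrt(pmax(diag(vcov_par)[9L + seq_len(Q)], 0))
        xi_ci <- cbind(xi = p$xi,
                       lo = exp(log(p$xi) - 1.96 * se_lxi),
                       hi = exp(log(p$xi) + 1.96 * se_lxi))
      }
    }
    if (!hessian_ok) {
      warning("observed information not invertible: standard errors unavailable")
    }
  }
  structure(list(params = params, se = se_vec, vcov = vcov_par,
                 xi_ci = xi_ci, loglik = -opt$objective,
                 converged = converged, hessian_ok = hessian_ok,
                 nodes = nodes, n = pre$n, n_events = sum(pre$event),
                 dataset = dataset, par = opt$par, centering = cen),
            class = c("qol_spm", "qol_fit"))
}

#' @export
coef.qol_spm <- function(object, ...) {
  c(object$params$lmm$beta, gamma = object$params$gamma,
    alpha = object$params$alpha)
}

#' @export
logLik.qol_spm <- function(object, ...) {
  structure(object$loglik, df = 9L + length(object$params$xi),
            class = "logLik")
}

#' @export
vcov.qol_spm <- function(object, ...) object$vcov

#' @export
predict.qol_spm <- function(object, arm = 0, times = NULL, ...) {
  if (is.null(times)) times <- object$dataset$schedule$times
  predict_mean(object$params$lmm, arm, times)
}

#' @export
print.qol_spm <- function(x, ...) {
  cat("Shared-parameter joint model, n = ", x$n, " (", x$n_events,
      " dropout events), logLik = ", format(x$loglik), "\n", sep = "")
  est <- coef(x)
  if (x$hessian_ok) {
    print(wald_table(est, x$se))
  } else {
    print(est)
    cat("(standard errors unavailable: information matrix not invertible)\n")
  }
  cat("baseline hazard levels:", format(x$params$xi, digits = 3), "\n")
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.qol_spm <- function(object, ...) {
  tab <- if (object$hessian_ok) wald_table(coef(object), object$se) else NULL
  out <- list(coef = coef(object), wald = tab, xi_ci = object$xi_ci,
              sigma2 = object$params$lmm$sigma2, G = object$params$lmm$G,
              loglik = object$loglik, converged = object$converged,
              hessian_ok = object$hessian_ok,
              hr_10pt = dropout_hazard_ratio(object$params$alpha, -10))
  class(out) <- "summary.qol_spm"
  out
}

#' @export
print.summary.qol_spm <- function(x, ...) {
  cat("Shared-parameter joint model\n\n")
  if (!is.null(x$wald)) print(x$wald) else print(x$coef)
  cat("\nHazard ratio for a 10-point score decrease:",
      format(x$hr_10pt, digits = 4), "\n")
  if (!is.null(x$xi_ci)) {
    cat("\nBaseline hazard (log-scale Wald intervals):\n")
    print(x$xi_ci)
  }
  cat("\nLog-likelihood:", format(x$loglik), "\n")
  invisible(x)
}
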