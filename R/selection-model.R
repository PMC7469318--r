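#' Dropout-logistic parameters of the selection model
#'
#' The selection model factorizes the joint law of scores and dropout as
#' (marginal score distribution) x (dropout given scores), and models the
#' discrete-time dropout hazard at visit j by the logistic regression
#' \deqn{\mathrm{logit}\, P(D_i = j \mid D_i \ge j) =
#'   \psi_0 + \psi_1 Y_i(t_j) + \psi_2 Y_i(t_{j+1})}
#' on the last observed and the current (possibly unobserved) score. A
#' non-zero `psi1` is evidence for dropout depending on the observed past
#' (MAR); a non-zero `psi2` for dependence on the unobserved current score
#' (MNAR, informative dropout). Coefficients are per raw point on the
#' 0-100 score scale.
#'
#' @param psi0 Logit intercept.
#' @param psi1 Coefficient of the last observed score (per point).
#' @param psi2 Coefficient of the current, possibly unobserved score
#'   (per point).
#' @return An object of class `dk_params`.
#' @export
dk_params <- function(psi0 = 0, psi1 = 0, psi2 = 0) {
  psi <- c(psi0 = psi0, psi1 = psi1, psi2 = psi2)
  if (any(!is.finite(psi))) stop("psi must be finite", call. = FALSE)
  structure(list(psi = psi), class = "dk_params")
}

#' @export
print.dk_params <- function(x, ...) {
  cat(sprintf("Dropout logistic: psi0 = %.4g, psi1 = %.4g, psi2 = %.4g\n",
              x$psi[1], x$psi[2], x$psi[3]))
  invisible(x)
}

#' Discrete-time dropout hazard
#'
#' Inverse-logit of `psi0 + psi1 * y_prev + psi2 * y_curr`; vectorized.
#'
#' @param dk A [dk_params()] object.
#' @param y_prev Last observed score(s), points.
#' @param y_curr Current score(s), points.
#' @return Probabilit(y/ies) in (0, 1).
#' @examples
#' dk_hazard(dk_params(-0.808, -0.005, 0.005), 50, 50)  # 0.3083
#' @export
dk_hazard <- function(dk, y_prev, y_curr) {
  stopifnot(inherits(dk, "dk_params"))
  unname(stats::plogis(dk$psi[1L] + dk$psi[2L] * y_prev +
                         dk$psi[3L] * y_curr))
}

#' Conditional distribution of the next score given the observed history
#'
#' Under the LMM the scores at the observed visits and the next visit are
#' jointly normal; this returns the Gaussian conditional moments of the
#' next score given the history, by the Schur complement of the observed
#' block.
#'
#' @param params An [lmm_params()] object.
#' @param arm 0 or 1.
#' @param observed Numeric vector of observed scores (visits 1..d).
#' @param times Times (months) of the observed visits, same length.
#' @param next_time Time of the next (unobserved) visit.
#' @return List with `mean` and `var` of the next score.
#' @export
conditional_next_score <- function(params, arm, observed, times, next_time) {
  stopifnot(inherits(params, "lmm_params"),
            length(observed) == length(times), length(observed) >= 1L)
  mm <- marginal_moments(params, arm, c(times, next_time))
  d <- length(observed)
  V11 <- mm$cov[seq_len(d), seq_len(d), drop = FALSE]
  v12 <- mm$cov[seq_len(d), d + 1L]
  w <- tryCatch(solve(V11, v12), error = function(e) {
    stop("singular observed-block covariance", call. = FALSE)
  })
  list(mean = unname(mm$mean[d + 1L] + sum((observed - mm$mean[seq_len(d)]) * w)),
       var = unname(mm$cov[d + 1L, d + 1L] - sum(v12 * w)))
}

## grouped pre-computation for the SM likelihood: subjects grouped by
## (dropout index, arm); within a group the observed-block covariance,
## its Cholesky and the conditional weights for the next visit are shared.
sm_prepare <- function(dataset) {
  stopifnot(inherits(dataset, "trial_data"))
  if (!is_monotone(dataset)) {
    stop("the selection model requires monotone missingness; ",
         "apply monotonize() first", call. = FALSE)
  }
  J <- dataset$schedule$J
  times <- dataset$schedule$times
  key <- paste(dataset$dropout, dataset$arm)
  idx <- split(seq_len(n_subjects(dataset)), key)
  groups <- lapply(idx, function(ii) {
    d <- dataset$dropout[ii[1L]]
    list(d = d, arm = dataset$arm[ii[1L]],
         Y = dataset$scores[ii, seq_len(d), drop = FALSE],
         tt = times[seq_len(min(d + 1L, J))], m = length(ii))
  })
  list(groups = groups, J = J, times = times, n = n_subjects(dataset))
}

sm_loglik_pre <- function(lmm, dk, pre, gh1) {
  sm_loglik_cpp(pre$groups, pre$J, unname(lmm$beta), lmm$G, lmm$sigma2,
                unname(dk$psi), gh1$x, gh1$w)
}

#' Joint log-likelihood of the selection model
#'
#' Sum over subjects of the observed-score normal log-density, the
#' log-probabilities of staying in between observed visits, and - for
#' dropouts before the last visit - the log of the dropout probability
#' marginalized over the unobserved next score,
#' \eqn{\int h(y_d, y)\,\phi(y; \mu_{d+1|1..d}, v_{d+1|1..d})\,dy},
#' evaluated by Gauss-Hermite quadrature on the conditional-normal scale.
#' Completers contribute density and stay-in factors only.
#'
#' @param lmm An [lmm_params()] object.
#' @param dk A [dk_params()] object.
#' @param dataset A monotone [trial_data()] object (see [monotonize()]).
#' @param nodes Number of Gauss-Hermite nodes for the dropout integral.
#' @return Scalar log-likelihood.
#' @export
sm_loglik <- function(lmm, dk, dataset, nodes = 30) {
  stopifnot(inherits(lmm, "lmm_params"), inherits(dk, "dk_params"))
  pre <- sm_prepare(dataset)
  sm_loglik_pre(lmm, dk, pre, pracma::gaussHermite(nodes))
}

#' Fit the Diggle-Kenward selection model
#'
#' Maximizes the joint likelihood of [sm_loglik()] over the LMM parameters
#' and the dropout-logistic coefficients together, with a quasi-Newton
#' optimizer on the unconstrained scale (log-Cholesky variance components).
#' Initialization is the ML LMM fit plus the constant-hazard (MCAR)
#' logistic fit with `psi1 = psi2 = 0`. Standard errors come from the
#' numerically differentiated observed information; when that matrix cannot
#' be inverted - a known practical failure mode of this model - the fit is
#' returned with `hessian_ok = FALSE` and a warning.
#'
#' @param dataset A monotone [trial_data()] object.
#' @param init Optional list with elements `lmm` ([lmm_params()]) and `dk`
#'   ([dk_params()]) used as starting values.
#' @param nodes Gauss-Hermite nodes for the dropout integral; default 30.
#' @param se Compute standard errors; default TRUE.
#' @param control Passed to [stats::nlminb()].
#' @return Object of class `c("qol_sm", "qol_fit")`: `params` (an
#'   [lmm_params()]), `dk` ([dk_params()]), `se`, `vcov`, `loglik`,
#'   `converged`, `hessian_ok`.
#' @export
fit_sm <- function(dataset, init = NULL, nodes = 30, se = TRUE,
                   control = list()) {
  pre <- sm_prepare(dataset)
  gh1 <- pracma::gaussHermite(nodes)
  J <- pre$J
  n_drop <- sum(dataset$dropout < J)
  if (n_drop == 0L) {
    warning("no dropouts: psi1/psi2 unidentified, psi0 driven to its bound")
  }
  user_init <- !is.null(init)
  if (!user_init) {
    ml <- fit_lmm(dataset, method = "ML")
    ## observable MAR logistic: dropout indicator on last observed score
    ## over at-risk person-visits
    ev <- list(); yp <- list()
    for (i in seq_len(n_subjects(dataset))) {
      d <- dataset$dropout[i]
      jj <- seq_len(min(d, J - 1L))
      ev[[i]] <- as.integer(d < J & jj == d)
      yp[[i]] <- dataset$scores[i, jj]
    }
    ev <- unlist(ev); yp <- unlist(yp)
    mar <- tryCatch(
      stats::glm.fit(cbind(1, yp), ev, family = stats::binomial())$coefficients,
      error = function(e) c(stats::qlogis(max(mean(ev), 1e-4)), 0))
    init <- list(lmm = ml$params, dk = dk_params(mar[1L], mar[2L], 0))
  }
  start <- c(unname(init$lmm$beta),
             vc_to_theta(init$lmm$G, init$lmm$sigma2),
             unname(init$dk$psi))
  unpack <- function(par) {
    vc <- theta_to_vc(par[4:7])
    list(lmm = list(beta = stats::setNames(par[1:3],
                                           c("beta0", "beta1", "beta2")),
                    G = vc$G, sigma2 = vc$sigma2),
         dk = list(psi = par[8:10]))
  }
  nll_with <- function(gh) {
    function(par) {
      p <- unpack(par)
      lmmp <- structure(p$lmm, class = "lmm_params")
      dkp <- structure(list(psi = p$dk$psi), class = "dk_params")
      ll <- sm_loglik_pre(lmmp, dkp, pre, gh)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  nll <- nll_with(gh1)
  lo <- c(rep(-1e4, 3), rep(-15, 3), -15, -20, -5, -5)
  hi <- c(rep(1e4, 3), rep(15, 3), 15, 20, 5, 5)
  pscale <- c(10, 1, 1, 1, 1, 1, 1, 1, 0.02, 0.02)
  ctl <- utils::modifyList(list(parscale = pscale, maxit = 300L,
                                factr = 1e7), control)
  ## the joint likelihood is multimodal in psi2 (a MAR-like mode at
  ## psi2 ~ 0 often coexists with the informative one): explore a small
  ## set of psi2 starts briefly, then polish the best
  ybar <- mean(unlist(lapply(pre$groups, function(g) g$Y)), na.rm = TRUE)
  psi2_starts <- if (user_init || n_drop == 0L) 0 else c(0, 0.04, -0.04)
  nll_coarse <- nll_with(pracma::gaussHermite(min(nodes, 12L)))
  explore <- lapply(psi2_starts, function(p2) {
    st <- start
    st[10L] <- start[10L] + p2
    st[8L] <- start[8L] - p2 * ybar
    stats::optim(st, nll_coarse, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = utils::modifyList(ctl, list(maxit = 12L)))
  })
  explore <- lapply(explore, function(o) { o$value <- nll(o$par); o })
  best <- explore[[which.min(vapply(explore, `[[`, numeric(1), "value"))]]
  opt <- stats::optim(best$par, nll, gr = fwd_grad(nll, pscale),
                      method = "L-BFGS-B",
                      lower = lo, upper = hi, control = ctl)
  converged <- opt$convergence == 0L && opt$value < 1e9
  opt$par <- opt$par; opt$objective <- opt$value
  p <- unpack(opt$par)
  params <- lmm_params(p$lmm$beta[1L], p$lmm$beta[2L], p$lmm$beta[3L],
                       p$lmm$G, p$lmm$sigma2)
  dk <- dk_params(p$dk$psi[1L], p$dk$psi[2L], p$dk$psi[3L])
  se_vec <- rep(NA_real_, 6L)
  names(se_vec) <- c("beta0", "beta1", "beta2", "psi0", "psi1", "psi2")
  vcov_par <- NULL; hessian_ok <- FALSE
  if (se) {
    H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
    if (!is.null(H)) {
      vcov_par <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_par) && all(diag(vcov_par)[c(1:3, 8:10)] > 0)) {
        hessian_ok <- TRUE
        se_vec[] <- sqrt(diag(vcov_par)[c(1:3, 8:10)])
      }
    }
    if (!hessian_ok) {
      warning("observed information not invertible: standard errors unavailable")
    }
  }
  structure(list(params = params, dk = dk, se = se_vec, vcov = vcov_par,
                 loglik = -opt$objective, converged = converged,
                 hessian_ok = hessian_ok, nodes = nodes, n = pre$n,
                 n_dropouts = n_drop, dataset = dataset, par = opt$par),
            class = c("qol_sm", "qol_fit"))
}

#' @export
coef.qol_sm <- function(object, ...) {
  c(object$params$beta, object$dk$psi)
}

#' @export
logLik.qol_sm <- function(object, ...) {
  structure(object$loglik, df = 10L, class = "logLik")
}

#' @export
vcov.qol_sm <- function(object, ...) object$vcov

#' @export
predict.qol_sm <- function(object, arm = 0, times = NULL, ...) {
  if (is.null(times)) times <- object$dataset$schedule$times
  predict_mean(object$params, arm, times)
}

#' @export
print.qol_sm <- function(x, ...) {
  cat("Diggle-Kenward selection model, n = ", x$n, " (", x$n_dropouts,
      " dropouts), logLik = ", format(x$loglik), "\n", sep = "")
  est <- coef(x)
  if (x$hessian_ok) {
    print(wald_table(est, x$se))
  } else {
    print(est)
    cat("(standard errors unavailable: information matrix not invertible)\n")
  }
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.qol_sm <- function(object, ...) {
  tab <- if (object$hessian_ok) wald_table(coef(object), object$se) else NULL
  out <- list(coef = coef(object), wald = tab,
              G = object$params$G, sigma2 = object$params$sigma2,
              loglik = object$loglik, converged = object$converged,
              hessian_ok = object$hessian_ok)
  class(out) <- "summary.qol_sm"
  out
}

#' @export
print.summary.qol_sm <- function(x, ...) {
  cat("Diggle-Kenward selection model\n\n")
  if (!is.null(x$wald)) print(x$wald) else print(x$coef)
  cat("\nA non-zero psi2 indicates dropout depending on the unobserved",
      "current score (informative dropout).\n")
  cat("Log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}
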