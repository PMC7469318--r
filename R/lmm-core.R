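## Internal machinery for the random-intercept/random-slope LMM:
##   y_i = X_i beta + Z_i b_i + eps_i,  b_i ~ N(0, G),  eps ~ N(0, sigma2 I)
## with Z_i = [1, t_ij]. The marginal likelihood is profiled: given the
## variance components, beta is the GLS solution, so the optimizer works on
## the 4 variance parameters only (log-Cholesky of G plus log sigma2).
##
## Subjects are grouped by identical (times, X) so each V_g = Z G Z' + s2 I
## is factorized once per group; with planned visit times and monotone
## dropout there are at most 2*J*(number of fixed-effect strata) groups.

## theta = (log L11, L21, log L22, log sigma2); G = L L'
theta_to_vc <- function(theta) {
  L <- matrix(c(exp(theta[1L]), theta[2L], 0, exp(theta[3L])), 2L, 2L)
  list(G = L %*% t(L), sigma2 = exp(theta[4L]))
}

vc_to_theta <- function(G, sigma2) {
  L <- t(chol(G + diag(1e-10, 2L)))
  c(log(L[1L, 1L]), L[2L, 1L], log(L[2L, 2L]), log(sigma2))
}

## Build grouped sufficient statistics.
## subjects: list with per-subject numeric times, matrix X (d x p), vector y.
lmm_groups <- function(times_list, X_list, y_list) {
  n <- length(y_list)
  key <- vapply(seq_len(n), function(i) {
    paste(c(format(times_list[[i]], digits = 12),
            format(X_list[[i]], digits = 12)), collapse = ";")
  }, character(1))
  idx <- split(seq_len(n), key)
  groups <- lapply(idx, function(ii) {
    Y <- do.call(cbind, y_list[ii])
    list(times = times_list[[ii[1L]]], X = X_list[[ii[1L]]],
         Y = Y, sy = rowSums(Y), m = length(ii), subjects = ii)
  })
  N <- sum(lengths(y_list))
  p <- ncol(X_list[[1L]])
  list(groups = groups, N = N, p = p, n = n)
}

## Profiled evaluation at variance components: returns GLS beta, its
## information A = sum X'V^-1 X, and the ML/REML log-likelihood.
lmm_profile <- function(theta, gr, method = c("ML", "REML")) {
  method <- match.arg(method)
  vc <- theta_to_vc(theta)
  G <- vc$G; s2 <- vc$sigma2
  p <- gr$p
  A <- matrix(0, p, p); bvec <- numeric(p)
  quad_yy <- 0; logdet <- 0
  cache <- vector("list", length(gr$groups))
  for (k in seq_along(gr$groups)) {
    g <- gr$groups[[k]]
    Z <- cbind(1, g$times)
    V <- Z %*% G %*% t(Z) + diag(s2, length(g$times))
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Xs <- backsolve(R, g$X, transpose = TRUE)
    Ys <- backsolve(R, g$Y, transpose = TRUE)
    A <- A + g$m * crossprod(Xs)
    bvec <- bvec + crossprod(Xs, rowSums(Ys))
    quad_yy <- quad_yy + sum(Ys * Ys)
    logdet <- logdet + g$m * 2 * sum(log(diag(R)))
    cache[[k]] <- list(R = R)
  }
  beta <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  quad <- quad_yy - 2 * sum(bvec * beta) + drop(t(beta) %*% A %*% beta)
  ll <- -0.5 * (gr$N * log(2 * pi) + logdet + quad)
  if (method == "REML") {
    ldA <- determinant(A, logarithm = TRUE)$modulus
    ll <- ll + 0.5 * p * log(2 * pi) - 0.5 * ldA
  }
  list(beta = beta, A = A, loglik = as.numeric(ll), G = G, sigma2 = s2,
       cache = cache)
}

## Log-likelihood at *given* fixed effects (ML) or the restricted
## log-likelihood (REML; does not depend on beta). The ML branch is a
## direct evaluation, so it works even when the design is deficient for
## GLS profiling (e.g. a single subject).
lmm_loglik_at <- function(beta, theta, gr, method = c("ML", "REML")) {
  method <- match.arg(method)
  if (method == "REML") {
    prof <- lmm_profile(theta, gr, method)
    if (is.null(prof)) return(-Inf)
    return(prof$loglik)
  }
  vc <- theta_to_vc(theta)
  ll <- 0
  for (g in gr$groups) {
    Z <- cbind(1, g$times)
    V <- Z %*% vc$G %*% t(Z) + diag(vc$sigma2, length(g$times))
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    E <- g$Y - drop(g$X %*% beta)
    U <- backsolve(R, E, transpose = TRUE)
    ll <- ll - 0.5 * g$m * (length(g$times) * log(2 * pi) +
                              2 * sum(log(diag(R)))) - 0.5 * sum(U * U)
  }
  ll
}

## Fit by maximizing the profiled criterion over theta.
lmm_core_fit <- function(times_list, X_list, y_list,
                         method = c("ML", "REML"),
                         start = NULL, control = list()) {
  method <- match.arg(method)
  gr <- lmm_groups(times_list, X_list, y_list)
  yall <- unlist(y_list)
  if (is.null(start)) {
    v0 <- stats::var(yall) + 1e-8
    tmax <- max(1, abs(unlist(times_list)))
    start <- c(0.5 * log(0.5 * v0), 0,
               0.5 * log(0.05 * v0 / tmax^2), log(0.5 * v0))
  }
  obj <- function(th) {
    prof <- lmm_profile(th, gr, method)
    if (is.null(prof) || !is.finite(prof$loglik)) return(1e10)
    -prof$loglik
  }
  lo <- c(-15, -50, -15, -15); hi <- c(15, 50, 15, 15)
  ctl <- utils::modifyList(list(rel.tol = 1e-10, iter.max = 300L,
                                eval.max = 600L), control)
  opt <- stats::nlminb(start, obj, lower = lo, upper = hi, control = ctl)
  converged <- opt$convergence == 0L && opt$objective < 1e9
  if (!converged) {
    ## deterministic jittered restarts
    for (k in 1:3) {
      st <- start + (k / 3) * c(1, 0.5, 1, 1) * (-1)^k
      o2 <- stats::nlminb(st, obj, lower = lo, upper = hi, control = ctl)
      if (o2$convergence == 0L && o2$objective < opt$objective) {
        opt <- o2; converged <- TRUE; break
      }
    }
  }
  prof <- lmm_profile(opt$par, gr, method)
  if (is.null(prof)) stop("variance-component optimization failed", call. = FALSE)
  vcov_fixed <- solve(prof$A)
  list(beta = prof$beta, G = prof$G, sigma2 = prof$sigma2,
       theta = opt$par, loglik = prof$loglik,
       vcov_fixed = vcov_fixed, se = sqrt(diag(vcov_fixed)),
       converged = converged, method = method, groups = gr,
       optim = opt)
}

## forward-difference gradient (p + 1 evaluations instead of optim's 2p)
fwd_grad <- function(fn, pscale, rel = 1e-7) {
  function(par) {
    f0 <- fn(par)
    vapply(seq_along(par), function(i) {
      h <- rel * max(abs(par[i]), pscale[i])
      pp <- par; pp[i] <- pp[i] + h
      (fn(pp) - f0) / h
    }, numeric(1))
  }
}

## Hessian by central differences of a gradient function
hess_from_grad <- function(gr, par, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    hj <- h * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + hj
    pm <- par; pm[j] <- pm[j] - hj
    H[, j] <- (gr(pp) - gr(pm)) / (2 * hj)
  }
  (H + t(H)) / 2
}

## Empirical-Bayes modes and curvatures of the random effects given a fit:
## posterior of b_i is N(G Z' V^-1 r_i, (Z'Z/s2 + G^-1)^-1).
lmm_eb_modes <- function(fit, times_list, X_list, y_list) {
  G <- fit$G; s2 <- fit$sigma2
  n <- length(y_list)
  Ginv <- solve(G + diag(1e-12, 2L))
  modes <- matrix(0, n, 2L)
  covs <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- times_list[[i]]
    Z <- cbind(1, tt)
    V <- Z %*% G %*% t(Z) + diag(s2, length(tt))
    r <- y_list[[i]] - drop(X_list[[i]] %*% fit$beta)
    modes[i, ] <- drop(G %*% t(Z) %*% solve(V, r))
    covs[[i]] <- solve(crossprod(Z) / s2 + Ginv)
  }
  list(modes = modes, covs = covs)
}
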