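#' Dropout pattern scheme
#'
#' Maps the dropout index D (last available visit, 1..J) to a pattern
#' label. The default four-pattern scheme for the eight-visit schedule
#' groups last measurements at V0-V2 (pattern 1, dropout during/just after
#' treatment), V3-V4 (pattern 2), V5 (pattern 3), and V6-V7 (pattern 4,
#' late dropouts merged with completers).
#'
#' @param sets List of integer vectors partitioning `1:J` into patterns, in
#'   pattern order.
#' @param J Number of planned visits.
#' @return Object of class `pattern_scheme` with `K`, `sets` and `map`
#'   (length-J vector giving the pattern of each dropout index).
#' @examples
#' pattern_scheme()                      # the default 4-pattern scheme
#' pattern_scheme(list(1:4, 5:8), J = 8) # early vs late dropout
#' @export
pattern_scheme <- function(sets = list(1:3, 4:5, 6L, 7:8), J = 8L) {
  sets <- lapply(sets, as.integer)
  all_d <- sort(unlist(sets))
  if (!identical(all_d, seq_len(J))) {
    stop("'sets' must partition 1:J", call. = FALSE)
  }
  map <- integer(J)
  for (k in seq_along(sets)) map[sets[[k]]] <- k
  structure(list(K = length(sets), sets = sets, map = map, J = J),
            class = "pattern_scheme")
}

#' @export
print.pattern_scheme <- function(x, ...) {
  cat("Dropout pattern scheme,", x$K, "patterns:\n")
  for (k in seq_len(x$K)) {
    cat("  pattern", k, ": last visit index in {",
        paste(x$sets[[k]], collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Assign dropout patterns and estimate their proportions
#'
#' Labels each subject by the pattern containing its dropout index and
#' estimates the pattern probabilities by the sample proportions
#' `pi_k = n_k / n`, with multinomial covariance
#' `(diag(pi) - pi pi') / n`.
#'
#' @param dataset A [trial_data()] object.
#' @param scheme A [pattern_scheme()].
#' @return List with `labels` (per subject), `n_k`, `pi`, `vcov_pi`.
#' @export
assign_patterns <- function(dataset, scheme = pattern_scheme(J = dataset$schedule$J)) {
  stopifnot(inherits(dataset, "trial_data"), inherits(scheme, "pattern_scheme"))
  if (scheme$J != dataset$schedule$J) {
    stop("scheme defined for a different number of visits", call. = FALSE)
  }
  labels <- scheme$map[dataset$dropout]
  n <- length(labels)
  n_k <- tabulate(labels, nbins = scheme$K)
  if (any(n_k == 0L)) {
    warning("empty pattern(s): ",
            paste(which(n_k == 0L), collapse = ", "),
            " (a fit will drop them and renormalize)")
  }
  pi_hat <- n_k / n
  list(labels = labels, n_k = n_k, pi = pi_hat,
       vcov_pi = (diag(pi_hat) - tcrossprod(pi_hat)) / n)
}

#' Fit the pattern-mixture model
#'
#' Factorizes the joint law as (pattern probability) x (scores given
#' pattern): pattern proportions are multinomial, and within patterns the
#' score follows the LMM with pattern-specific fixed effects
#' \eqn{\beta_0^k, \beta_1^k, \beta_2^k}. In `"shared"` mode (default) this
#' is one mixed model with pattern-indexed fixed effects and common
#' variance components; `"stratified"` fits an independent LMM per pattern.
#' Marginal effects are the proportion-weighted sums
#' \eqn{\beta_l = \sum_k \beta_l^k \pi_k} with delta-method intervals (see
#' [marginalize_pmm()]); they implicitly extrapolate each pattern's linear
#' trajectory beyond its dropout.
#'
#' Patterns with fewer than 2 subjects or a single distinct observation
#' time are dropped with a warning and the proportions renormalized; a
#' pattern observed in only one arm loses its interaction term (treated as
#' 0 in marginalization) with a warning.
#'
#' @param dataset A [trial_data()] object.
#' @param scheme A [pattern_scheme()].
#' @param variance_mode `"shared"` or `"stratified"`.
#' @param method `"REML"` (default) or `"ML"` for the LMM part.
#' @return Object of class `c("qol_pmm", "qol_fit")`: `coef_k` (K x 3
#'   matrix of pattern effects), `vcov_k` (their joint covariance), `pi`,
#'   `vcov_pi`, `marginal` (Wald table of marginalized effects), `G`,
#'   `sigma2`, `loglik`, `dropped_patterns`, `renormalized`.
#' @export
fit_pmm <- function(dataset, scheme = pattern_scheme(J = dataset$schedule$J),
                    variance_mode = c("shared", "stratified"),
                    method = c("REML", "ML")) {
  variance_mode <- match.arg(variance_mode)
  method <- match.arg(method)
  pat <- suppressWarnings(assign_patterns(dataset, scheme))
  K <- scheme$K
  ## retain patterns with enough support
  ok <- logical(K)
  for (k in seq_len(K)) {
    ii <- which(pat$labels == k)
    if (length(ii) < 2L) next
    nt <- length(unique(unlist(lapply(ii, function(i) {
      which(!is.na(dataset$scores[i, ]))
    }))))
    ok[k] <- nt >= 2L
  }
  dropped <- which(!ok)
  renormalized <- length(dropped) > 0L
  if (renormalized) {
    warning("dropping pattern(s) without usable support: ",
            paste(dropped, collapse = ", "),
            "; proportions renormalized for marginalization")
  }
  kept <- which(ok)
  ## interaction estimable only if both arms present in the pattern
  has_int <- vapply(kept, function(k) {
    a <- dataset$arm[pat$labels == k]
    length(unique(a)) == 2L
  }, logical(1))
  if (any(!has_int)) {
    warning("pattern(s) ", paste(kept[!has_int], collapse = ", "),
            " observed in a single arm: interaction dropped (0 in marginalization)")
  }
  ## column layout: for each kept pattern, intercept, time, (arm x time)
  cols <- list(); cn <- character(0)
  for (j in seq_along(kept)) {
    k <- kept[j]
    cn <- c(cn, paste0(c("beta0_", "beta1_"), k),
            if (has_int[j]) paste0("beta2_", k))
  }
  p_tot <- length(cn)
  times <- dataset$schedule$times
  sub <- which(pat$labels %in% kept)
  tl <- list(); Xl <- list(); yl <- list(); nsub <- 0L
  for (i in sub) {
    obs <- which(!is.na(dataset$scores[i, ]))
    tt <- times[obs]
    k <- pat$labels[i]; j <- match(k, kept)
    X <- matrix(0, length(tt), p_tot)
    base <- match(paste0("beta0_", k), cn)
    X[, base] <- 1
    X[, base + 1L] <- tt
    if (has_int[j]) X[, base + 2L] <- dataset$arm[i] * tt
    nsub <- nsub + 1L
    tl[[nsub]] <- tt; Xl[[nsub]] <- X; yl[[nsub]] <- dataset$scores[i, obs]
  }
  if (variance_mode == "shared") {
    core <- lmm_core_fit(tl, Xl, yl, method = method)
    est <- stats::setNames(core$beta, cn)
    Vb <- core$vcov_fixed
    G <- core$G; sigma2 <- core$sigma2; loglik <- core$loglik
    converged <- core$converged
  } else {
    ## independent LMM per pattern; block-diagonal joint covariance
    est <- stats::setNames(rep(NA_real_, p_tot), cn)
    Vb <- matrix(0, p_tot, p_tot, dimnames = list(cn, cn))
    loglik <- 0; converged <- TRUE
    G <- NULL; sigma2 <- NULL
    for (j in seq_along(kept)) {
      k <- kept[j]
      idc <- grep(paste0("_", k, "$"), cn)
      sel <- which(pat$labels == k)
      tk <- list(); Xk <- list(); yk <- list()
      for (m in seq_along(sel)) {
        i <- sel[m]
        obs <- which(!is.na(dataset$scores[i, ]))
        tt <- times[obs]
        tk[[m]] <- tt
        Xk[[m]] <- if (has_int[j]) cbind(1, tt, dataset$arm[i] * tt) else cbind(1, tt)
        yk[[m]] <- dataset$scores[i, obs]
      }
      ck <- lmm_core_fit(tk, Xk, yk, method = method)
      est[idc] <- ck$beta
      Vb[idc, idc] <- ck$vcov_fixed
      loglik <- loglik + ck$loglik
      converged <- converged && ck$converged
      if (j == 1L) { G <- ck$G; sigma2 <- ck$sigma2 }
    }
  }
  ## assemble K x 3 coefficient matrix (dropped/absent terms = 0, flagged NA->0)
  coef_k <- matrix(0, K, 3L,
                   dimnames = list(paste0("pattern", seq_len(K)),
                                   c("beta0", "beta1", "beta2")))
  for (j in seq_along(kept)) {
    k <- kept[j]
    coef_k[k, 1L] <- est[paste0("beta0_", k)]
    coef_k[k, 2L] <- est[paste0("beta1_", k)]
    if (has_int[j]) coef_k[k, 3L] <- est[paste0("beta2_", k)]
  }
  pi_use <- pat$pi
  if (renormalized) {
    pi_use[dropped] <- 0
    pi_use <- pi_use / sum(pi_use)
  }
  ## arm-specific proportions (optional weighting in marginalize_pmm)
  pi_arm <- sapply(0:1, function(a) {
    la <- pat$labels[dataset$arm == a]
    nk <- tabulate(la, nbins = K)
    nk[dropped] <- 0L
    if (sum(nk) == 0L) rep(NA_real_, K) else nk / sum(nk)
  })
  n_arm <- c(sum(dataset$arm == 0L & pat$labels %in% kept),
             sum(dataset$arm == 1L & pat$labels %in% kept))
  fit <- structure(list(coef_k = coef_k, vcov_k = Vb, coef_names = cn,
                        kept = kept, has_int = has_int,
                        pi = pi_use, pi_raw = pat$pi, n_k = pat$n_k,
                        vcov_pi = (diag(pi_use) - tcrossprod(pi_use)) /
                          length(sub),
                        pi_arm = pi_arm, n_arm = n_arm,
                        G = G, sigma2 = sigma2, loglik = loglik,
                        variance_mode = variance_mode, method = method,
                        scheme = scheme, converged = converged,
                        dropped_patterns = dropped,
                        renormalized = renormalized,
                        n = length(sub), dataset = dataset),
                   class = c("qol_pmm", "qol_fit"))
  fit$marginal <- marginalize_pmm(fit)
  fit
}

#' Marginalize pattern-specific effects
#'
#' Combines the pattern-specific fixed effects into marginal effects
#' \eqn{\beta_l = \sum_k \beta_l^k \pi_k} (l = 0, 1, 2). The delta-method
#' variance treats the effect estimates and the multinomial proportions as
#' independent: `w' S_beta w + beta' S_pi beta` with `w = pi`. With
#' `weights = "by_arm"` the control-arm proportions weight the control
#' slope and the experimental-arm proportions the experimental slope (the
#' interaction is their difference); this alternative is provided because
#' overall-weight marginals and arm-specific marginals can differ
#' appreciably when dropout timing differs by arm.
#'
#' @param fit A `qol_pmm` fit.
#' @param weights `"overall"` (default) or `"by_arm"`.
#' @return Wald table (data frame) of the marginal `beta0`, `beta1`,
#'   `beta2`.
#' @export
marginalize_pmm <- function(fit, weights = c("overall", "by_arm")) {
  weights <- match.arg(weights)
  stopifnot(inherits(fit, "qol_pmm"))
  K <- nrow(fit$coef_k)
  ## expand vcov of estimated coefficients to the full 3K layout
  full <- matrix(0, 3L * K, 3L * K)
  pos <- function(k, l) (k - 1L) * 3L + l  # l = 1..3
  map_idx <- integer(0); est_idx <- integer(0)
  for (nm_i in seq_along(fit$coef_names)) {
    nm <- fit$coef_names[nm_i]
    l <- as.integer(substr(nm, 5L, 5L)) + 1L
    k <- as.integer(sub("^beta._", "", nm))
    map_idx <- c(map_idx, pos(k, l)); est_idx <- c(est_idx, nm_i)
  }
  full[map_idx, map_idx] <- fit$vcov_k[est_idx, est_idx]
  beta_vec <- as.vector(t(fit$coef_k))  # order: (k1: b0,b1,b2), (k2: ...), ...
  if (weights == "overall") {
    w <- fit$pi
    Spi <- fit$vcov_pi
    out <- lapply(1:3, function(l) {
      idx <- pos(seq_len(K), l)
      bl <- beta_vec[idx]
      estimate <- sum(bl * w)
      v <- drop(t(w) %*% full[idx, idx] %*% w) + drop(t(bl) %*% Spi %*% bl)
      c(estimate = estimate, se = sqrt(v))
    })
    est <- vapply(out, `[`, numeric(1), 1L)
    ses <- vapply(out, `[`, numeric(1), 2L)
  } else {
    w0 <- fit$pi_arm[, 1L]; w1 <- fit$pi_arm[, 2L]
    if (anyNA(w0) || anyNA(w1)) {
      stop("arm-specific weights unavailable (an arm has no subjects)",
           call. = FALSE)
    }
    S0 <- (diag(w0) - tcrossprod(w0)) / fit$n_arm[1L]
    S1 <- (diag(w1) - tcrossprod(w1)) / fit$n_arm[2L]
    i0 <- pos(seq_len(K), 1L); i1 <- pos(seq_len(K), 2L); i2 <- pos(seq_len(K), 3L)
    b0 <- beta_vec[i0]; b1 <- beta_vec[i1]; b2 <- beta_vec[i2]
    est0 <- sum(b0 * fit$pi)
    v0 <- drop(t(fit$pi) %*% full[i0, i0] %*% fit$pi) +
      drop(t(b0) %*% fit$vcov_pi %*% b0)
    slope_c <- sum(b1 * w0)
    vc_ <- drop(t(w0) %*% full[i1, i1] %*% w0) + drop(t(b1) %*% S0 %*% b1)
    ## experimental slope: sum w1 (b1 + b2); gradient in (b1, b2) is (w1, w1)
    slope_e <- sum(w1 * (b1 + b2))
    g <- c(w1, w1)
    ve <- drop(t(g) %*% full[c(i1, i2), c(i1, i2)] %*% g) +
      drop(t(b1 + b2) %*% S1 %*% (b1 + b2))
    ## interaction = slope_e - slope_c; effect-estimate parts covary
    gi <- c(-w0 + w1, w1)  # d/d(b1), d/d(b2)
    vi <- drop(t(gi) %*% full[c(i1, i2), c(i1, i2)] %*% gi) +
      drop(t(b1) %*% S0 %*% b1) + drop(t(b1 + b2) %*% S1 %*% (b1 + b2))
    est <- c(est0, slope_c, slope_e - slope_c)
    ses <- sqrt(c(v0, vc_, vi))
  }
  wald_table(stats::setNames(est, c("beta0", "beta1", "beta2")), ses)
}

#' @export
coef.qol_pmm <- function(object, ...) {
  stats::setNames(object$marginal$estimate, rownames(object$marginal))
}

#' @export
logLik.qol_pmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coef_names) + 4L,
            class = "logLik")
}

#' @export
vcov.qol_pmm <- function(object, ...) object$vcov_k

#' Predicted pattern and marginal trajectories
#'
#' @param object A `qol_pmm` fit.
#' @param arm 0 or 1.
#' @param times Times at which to evaluate; defaults to the schedule.
#' @param ... Unused.
#' @return Matrix with one row per pattern plus a `marginal` row; each
#'   pattern's straight line `beta0_k + (beta1_k + beta2_k * arm) t` is
#'   extrapolated over the whole grid, beyond that pattern's dropout.
#' @export
predict.qol_pmm <- function(object, arm = 0, times = NULL, ...) {
  if (is.null(times)) times <- object$dataset$schedule$times
  K <- nrow(object$coef_k)
  curves <- t(vapply(seq_len(K), function(k) {
    b <- object$coef_k[k, ]
    b[1L] + (b[2L] + b[3L] * arm) * times
  }, numeric(length(times))))
  rbind(curves, marginal = drop(object$pi %*% curves))
}

#' @export
print.qol_pmm <- function(x, ...) {
  cat("Pattern-mixture model (", x$variance_mode, " variance, ", x$method,
      "), n = ", x$n, ", K = ", length(x$kept), " fitted pattern(s)\n",
      sep = "")
  cat("pattern proportions:", sprintf("%.3f", x$pi), "\n")
  cat("\nMarginal (proportion-weighted) effects:\n")
  print(x$marginal)
  if (x$renormalized) cat("NOTE: proportions renormalized after dropping pattern(s)\n")
  invisible(x)
}

#' @export
summary.qol_pmm <- function(object, ...) {
  out <- list(coef_k = object$coef_k, pi = object$pi, n_k = object$n_k,
              marginal = object$marginal,
              marginal_by_arm = tryCatch(
                marginalize_pmm(object, weights = "by_arm"),
                error = function(e) NULL),
              G = object$G, sigma2 = object$sigma2,
              loglik = object$loglik, variance_mode = object$variance_mode)
  class(out) <- "summary.qol_pmm"
  out
}

#' @export
print.summary.qol_pmm <- function(x, ...) {
  cat("Pattern-mixture model (", x$variance_mode, " variance components)\n\n",
      sep = "")
  cat("Pattern-specific fixed effects:\n"); print(x$coef_k)
  cat("\nPattern proportions:", sprintf("%.3f", x$pi), "\n")
  cat("\nMarginal effects (overall weights):\n"); print(x$marginal)
  if (!is.null(x$marginal_by_arm)) {
    cat("\nMarginal effects (arm-specific weights):\n")
    print(x$marginal_by_arm)
  }
  invisible(x)
}
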