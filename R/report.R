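#' Fit and compare the four models on one dataset
#'
#' Fits the LMM, the selection model, the pattern-mixture model and the
#' shared-parameter model (or a subset) to one trial dataset and tabulates
#' estimates, 95% Wald confidence intervals and two-sided normal-reference
#' p-values, the comparison surface of a methods paper. A model that fails
#' is captured with its error message without aborting the others.
#'
#' @param dataset A [trial_data()] object (monotonized automatically for
#'   the selection model).
#' @param models Character subset of `c("lmm", "sm", "pmm", "spm")`.
#' @param scheme [pattern_scheme()] for the PMM.
#' @param knots Baseline-hazard knots for the SPM.
#' @param sm_nodes,spm_nodes Quadrature sizes.
#' @param lmm_method `"REML"` (default) or `"ML"` for the standalone LMM
#'   and PMM.
#' @return Object of class `qol_comparison`: `fits` (named list),
#'   `table` (long data frame: model, parameter, estimate, se, ci_lo,
#'   ci_hi, p), `loglik`, `converged`, `errors`.
#' @examples
#' tr <- simulate_trial(sim_config(n_per_arm = 50, mechanism = "mnar_dk",
#'                                 seed = 3))
#' cmp <- run_comparison(tr$dataset, models = c("lmm", "pmm"))
#' cmp$table
#' @export
run_comparison <- function(dataset,
                           models = c("lmm", "sm", "pmm", "spm"),
                           scheme = pattern_scheme(J = dataset$schedule$J),
                           knots = c(1.25, 3, 4, 6, 12, 24),
                           sm_nodes = 30, spm_nodes = 9,
                           lmm_method = "REML") {
  models <- match.arg(models, c("lmm", "sm", "pmm", "spm"),
                      several.ok = TRUE)
  mono <- monotonize(dataset)
  fits <- list(); errors <- list()
  for (m in models) {
    fits[[m]] <- tryCatch(switch(m,
      lmm = fit_lmm(dataset, method = lmm_method),
      sm  = fit_sm(mono, nodes = sm_nodes),
      pmm = fit_pmm(dataset, scheme = scheme, method = lmm_method),
      spm = fit_spm(mono, knots = knots, nodes = spm_nodes)),
      error = function(e) {
        errors[[m]] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("all models failed: ",
         paste(names(errors), unlist(errors), sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  rows <- list()
  add <- function(model, tab) {
    rows[[length(rows) + 1L]] <<- cbind(model = model,
                                        parameter = rownames(tab), tab)
  }
  for (m in names(fits)[ok]) {
    f <- fits[[m]]
    if (m == "pmm") {
      add(m, f$marginal)
      ck <- f$coef_k
      est <- stats::setNames(
        unlist(lapply(f$coef_names, function(nm) {
          l <- as.integer(substr(nm, 5, 5)) + 1L
          k <- as.integer(sub("^beta._", "", nm))
          ck[k, l]
        })), f$coef_names)
      add(m, wald_table(est, sqrt(diag(f$vcov_k))))
    } else {
      est <- coef(f)
      se <- if (!is.null(f$se)) f$se else rep(NA_real_, length(est))
      se <- se[seq_along(est)]
      add(m, wald_table(est, unname(se)))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab,
                 loglik = vapply(fits, function(f)
                   if (is.null(f)) NA_real_ else as.numeric(f$loglik),
                   numeric(1)),
                 converged = vapply(fits, function(f)
                   if (is.null(f)) NA else isTRUE(f$converged), logical(1)),
                 errors = errors, dataset = dataset),
            class = "qol_comparison")
}

#' @export
print.qol_comparison <- function(x, digits = 3, ...) {
  cat("Model comparison on", n_subjects(x$dataset), "subjects\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (length(x$errors)) {
    cat("\nFailed models:\n")
    for (m in names(x$errors)) cat("  ", m, ": ", x$errors[[m]], "\n", sep = "")
  }
  invisible(x)
}

#' Predicted trajectory and hazard curves across models
#'
#' Tabulates, on a time grid, the mean-score trajectory of every converged
#' fit by arm; for the pattern-mixture fit also the per-pattern straight
#' lines (extrapolated over the whole grid) and their proportion-weighted
#' marginal; for the shared-parameter fit also the fitted piecewise-
#' constant baseline hazard.
#'
#' @param fits Named list of fits as in `run_comparison()$fits` (or a
#'   `qol_comparison`).
#' @param schedule A [visit_schedule()] supplying the default grid.
#' @param times Optional time grid (months).
#' @return List with `trajectories` (data frame: model, arm, time, mean),
#'   `patterns` (PMM pattern curves, if present) and `baseline_hazard`
#'   (SPM step function, if present).
#' @export
trajectory_curves <- function(fits, schedule = visit_schedule(),
                              times = NULL) {
  if (inherits(fits, "qol_comparison")) fits <- fits$fits
  if (is.null(times)) times <- schedule$times
  out <- list()
  tra <- list()
  for (m in names(fits)) {
    f <- fits[[m]]
    if (is.null(f)) next
    for (a in 0:1) {
      mu <- switch(m,
                   pmm = drop(f$pi %*% predict(f, arm = a, times = times)[
                     seq_len(nrow(f$coef_k)), , drop = FALSE]),
                   predict(f, arm = a, times = times))
      tra[[length(tra) + 1L]] <- data.frame(model = m, arm = a,
                                            time = times, mean = mu)
    }
  }
  out$trajectories <- do.call(rbind, tra)
  if (!is.null(fits$pmm)) {
    pk <- list()
    K <- nrow(fits$pmm$coef_k)
    for (a in 0:1) {
      cur <- predict(fits$pmm, arm = a, times = times)
      for (k in seq_len(K + 1L)) {
        pk[[length(pk) + 1L]] <- data.frame(
          pattern = rownames(cur)[k], arm = a, time = times,
          mean = cur[k, ])
      }
    }
    out$patterns <- do.call(rbind, pk)
  }
  if (!is.null(fits$spm) && !isTRUE(fits$spm$degenerate)) {
    kn <- fits$spm$params$knots
    out$baseline_hazard <- data.frame(
      start = c(0, kn),
      end = c(kn, max(schedule$times)),
      xi = fits$spm$params$xi)
  }
  out
}

#' @export
plot.qol_comparison <- function(x, arm = 0, times = NULL, ...) {
  tc <- trajectory_curves(x, schedule = x$dataset$schedule, times = times)
  tra <- tc$trajectories[tc$trajectories$arm == arm, ]
  models <- unique(tra$model)
  graphics::matplot(
    x = unique(tra$time),
    y = sapply(models, function(m) tra$mean[tra$model == m]),
    type = "l", lty = seq_along(models), col = seq_along(models),
    xlab = "months", ylab = "mean score",
    main = paste("Predicted trajectories, arm", arm), ...)
  graphics::legend("topright", legend = models, lty = seq_along(models),
                   col = seq_along(models), bty = "n")
  invisible(x)
}
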