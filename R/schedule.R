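#' Planned visit schedule
#'
#' Defines the planned assessment times of a longitudinal HRQoL study. All
#' model design matrices use these planned times, not the observed ones. The
#' default is the eight-visit oncology schedule: baseline, during treatment
#' (months 1.25 and 3), month 4, and follow-up at months 6, 12, 24 and 36.
#'
#' @param times Numeric vector of strictly increasing visit times in months.
#' @param labels Optional character vector of visit names; defaults to
#'   `V0..V{J-1}`.
#' @return An object of class `visit_schedule`: a list with `times`, `labels`
#'   and `J` (the number of planned visits).
#' @examples
#' visit_schedule()
#' visit_schedule(c(0, 6, 12))
#' @export
visit_schedule <- function(times = c(0, 1.25, 3, 4, 6, 12, 24, 36),
                           labels = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2L) {
    stop("a visit schedule needs at least two planned visits", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("visit times must be finite and strictly increasing", call. = FALSE)
  }
  J <- length(times)
  if (is.null(labels)) {
    labels <- paste0("V", seq_len(J) - 1L)
  }
  if (length(labels) != J) {
    stop("'labels' must have one entry per visit", call. = FALSE)
  }
  structure(list(times = times, labels = as.character(labels), J = J),
            class = "visit_schedule")
}

#' @export
print.visit_schedule <- function(x, ...) {
  cat("Visit schedule:", x$J, "planned visits\n")
  print(stats::setNames(x$times, x$labels))
  invisible(x)
}

## match observed times to schedule indices; NA where no match within tol
match_schedule_time <- function(time, schedule, tol = 0.01) {
  idx <- vapply(time, function(tt) {
    d <- abs(schedule$times - tt)
    j <- which.min(d)
    if (d[j] <= tol) j else NA_integer_
  }, integer(1))
  idx
}
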