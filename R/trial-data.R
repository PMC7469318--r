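#' Trial dataset of longitudinal HRQoL scores
#'
#' Container for a two-arm trial with scores on a 0-100 scale observed at the
#' planned visits of a [visit_schedule()]. Subjects with no available score
#' are excluded (the evaluable intent-to-treat rule: a subject is evaluable
#' when the score is available at least once) and counted in `n_excluded`.
#' The dropout index `D_i` of each retained subject is the largest visit
#' index with an available score.
#'
#' @param id Character or integer vector of subject identifiers (length n).
#' @param arm Binary vector (0 control, 1 experimental), length n.
#' @param scores n x J numeric matrix of scores, `NA` where missing.
#' @param schedule A [visit_schedule()]; its `J` must equal `ncol(scores)`.
#' @return An object of class `trial_data`: list with `id`, `arm`, `scores`,
#'   `dropout` (the index D_i per subject), `schedule`, `n_excluded`.
#' @seealso [read_trial_csv()], [monotonize()], [summarize_missingness()]
#' @examples
#' sch <- visit_schedule(c(0, 6, 12))
#' y <- rbind(c(50, 55, NA), c(60, NA, NA))
#' trial_data(c("a", "b"), c(0, 1), y, sch)
#' @export
trial_data <- function(id, arm, scores, schedule = visit_schedule()) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  n <- nrow(scores)
  if (length(id) != n || length(arm) != n) {
    stop("'id', 'arm' and rows of 'scores' must agree in length", call. = FALSE)
  }
  if (ncol(scores) != schedule$J) {
    stop("'scores' must have one column per planned visit", call. = FALSE)
  }
  arm <- as.integer(arm)
  if (any(is.na(arm)) || !all(arm %in% c(0L, 1L))) {
    stop("'arm' must be binary (0 control, 1 experimental)", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate subject identifiers", call. = FALSE)
  }
  avail <- !is.na(scores)
  keep <- rowSums(avail) > 0L
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(n_excluded, " subject(s) with no available score excluded")
    id <- id[keep]; arm <- arm[keep]
    scores <- scores[keep, , drop = FALSE]
    avail <- avail[keep, , drop = FALSE]
  }
  dropout <- apply(avail, 1L, function(a) max(which(a)))
  structure(list(id = as.character(id), arm = arm, scores = scores,
                 dropout = as.integer(dropout), schedule = schedule,
                 n_excluded = n_excluded),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  n <- length(x$id)
  cat("Trial dataset:", n, "evaluable subjects (",
      sum(x$arm == 0L), "control /", sum(x$arm == 1L), "experimental ),",
      x$schedule$J, "planned visits\n")
  cat("Available scores:", sum(!is.na(x$scores)), "of", n * x$schedule$J, "\n")
  cat("Completers (no dropout):", sum(x$dropout == x$schedule$J), "\n")
  if (x$n_excluded > 0L) cat("Excluded (never observed):", x$n_excluded, "\n")
  if (isTRUE(attr(x, "truncated"))) cat("Scores truncated to [0, 100]\n")
  invisible(x)
}

n_subjects <- function(x) length(x$id)

is_monotone <- function(x) {
  J <- x$schedule$J
  all(vapply(seq_len(n_subjects(x)), function(i) {
    obs <- which(!is.na(x$scores[i, ]))
    identical(obs, seq_len(x$dropout[i]))
  }, logical(1)))
}

#' Read a long-format score table
#'
#' Reads a delimited file with columns `subject_id, arm, time_months, score`
#' (one row per subject-visit) into a [trial_data()] object. Observed times
#' are matched to the schedule within +/- `tol` months; an empty score field
#' or the literal `NA` parse as missing, anything else non-numeric is an
#' error. Subjects whose rows are all missing are excluded with a message.
#'
#' @param path Path to a CSV file.
#' @param schedule A [visit_schedule()].
#' @param tol Visit-time matching tolerance in months.
#' @return A `trial_data` object.
#' @export
read_trial_csv <- function(path, schedule = visit_schedule(), tol = 0.01) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("subject_id", "arm", "time_months", "score")
  if (!all(need %in% names(raw))) {
    stop("file must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  tm <- suppressWarnings(as.numeric(raw$time_months))
  if (any(is.na(tm))) {
    stop("non-numeric time_months in row(s) ",
         paste(which(is.na(tm)), collapse = ", "), call. = FALSE)
  }
  j <- match_schedule_time(tm, schedule, tol)
  if (any(is.na(j))) {
    bad <- which(is.na(j))[1L]
    stop("row ", bad, ": visit time ", tm[bad],
         " does not match any scheduled visit", call. = FALSE)
  }
  sc_chr <- raw$score
  miss <- is.na(sc_chr) | sc_chr == "" | sc_chr == "NA"
  sc <- suppressWarnings(as.numeric(sc_chr))
  bad_sc <- !miss & is.na(sc)
  if (any(bad_sc)) {
    stop("non-numeric score in row(s) ",
         paste(which(bad_sc), collapse = ", "), call. = FALSE)
  }
  sc[miss] <- NA_real_
  arm_n <- suppressWarnings(as.numeric(raw$arm))
  if (any(is.na(arm_n)) || !all(arm_n %in% c(0, 1))) {
    stop("'arm' must be 0 or 1 for every row", call. = FALSE)
  }
  key <- paste(raw$subject_id, j, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate subject-visit row(s): ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  ids <- unique(raw$subject_id)
  arm_by_id <- tapply(arm_n, raw$subject_id, function(a) {
    if (length(unique(a)) > 1L) stop("subject with inconsistent arm", call. = FALSE)
    a[1L]
  })
  scores <- matrix(NA_real_, length(ids), schedule$J,
                   dimnames = list(ids, schedule$labels))
  scores[cbind(match(raw$subject_id, ids), j)] <- sc
  trial_data(ids, arm_by_id[ids], scores, schedule)
}

#' Write a trial dataset as a long-format CSV
#'
#' Inverse of [read_trial_csv()]: one row per subject-visit with columns
#' `subject_id, arm, time_months, score` (missing scores written as empty
#' fields). Reading the file back reproduces scores, arms and dropout
#' indices exactly.
#'
#' @param x A `trial_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  stopifnot(inherits(x, "trial_data"))
  J <- x$schedule$J
  n <- n_subjects(x)
  sc <- as.vector(t(x$scores))
  df <- data.frame(
    subject_id = rep(x$id, each = J),
    arm = rep(x$arm, each = J),
    time_months = rep(x$schedule$times, n),
    ## full double precision so that read -> write -> read is lossless
    score = ifelse(is.na(sc), "", formatC(sc, digits = 17, format = "g"))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Enforce monotone missingness
#'
#' The dropout models treat missingness as monotone: once a score is missing
#' it stays missing. Under `policy = "truncate_at_first_gap"` every score
#' after a subject's first internal gap is set missing and the dropout index
#' recomputed; `policy = "keep"` returns the dataset unchanged. The truncate
#' policy is this package's explicit convention for intermittent gaps, not a
#' recommendation.
#'
#' @param x A `trial_data` object.
#' @param policy `"truncate_at_first_gap"` or `"keep"`.
#' @return A `trial_data` object with strictly monotone missingness (under
#'   the truncate policy).
#' @examples
#' sch <- visit_schedule(c(0, 1, 2, 3))
#' d <- trial_data("s1", 0, matrix(c(50, 52, NA, 55), 1), sch)
#' monotonize(d)$dropout  # 2: visit 4 discarded after the gap at visit 3
#' @export
monotonize <- function(x, policy = c("truncate_at_first_gap", "keep")) {
  stopifnot(inherits(x, "trial_data"))
  policy <- match.arg(policy)
  if (policy == "keep") return(x)
  scores <- x$scores
  for (i in seq_len(nrow(scores))) {
    gap <- which(is.na(scores[i, ]))
    if (length(gap) && gap[1L] <= x$dropout[i]) {
      scores[i, gap[1L]:ncol(scores)] <- NA_real_
    }
  }
  out <- trial_data(x$id, x$arm, scores, x$schedule)
  out$n_excluded <- x$n_excluded
  attr(out, "truncated") <- attr(x, "truncated")
  out
}

#' Missingness and compliance summary
#'
#' Per-visit, per-arm score availability (compliance) and the distribution
#' of dropout by last available visit, the accounting a trial report shows
#' as its missing-data flow diagram. Percentages are rounded half-up to
#' integers; raw fractions are retained alongside.
#'
#' @param x A `trial_data` object.
#' @return An object of class `missingness_summary`: list with two data
#'   frames, `availability` (visit, arm, n_available, n_expected, compliance
#'   fraction and rounded pct) and `dropout` (last visit, arm, n_dropped,
#'   cumulative dropout fraction and rounded pct).
#' @export
summarize_missingness <- function(x) {
  stopifnot(inherits(x, "trial_data"))
  n <- n_subjects(x)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  J <- x$schedule$J
  round_half_up <- function(p) floor(p * 100 + 0.5)
  avail <- do.call(rbind, lapply(0:1, function(a) {
    sel <- x$arm == a
    data.frame(
      visit = x$schedule$labels,
      time = x$schedule$times,
      arm = a,
      n_available = colSums(!is.na(x$scores[sel, , drop = FALSE])),
      n_expected = sum(sel)
    )
  }))
  avail$compliance <- avail$n_available / ifelse(avail$n_expected > 0,
                                                 avail$n_expected, NA_real_)
  avail$compliance_pct <- round_half_up(avail$compliance)
  drp <- do.call(rbind, lapply(0:1, function(a) {
    sel <- x$arm == a
    nd <- tabulate(x$dropout[sel], nbins = J)
    # cumulative dropout: subjects whose last visit is <= j, among j < J;
    # completers (D = J) never count as dropped
    cum <- cumsum(nd)
    cum[J] <- cum[J] - nd[J]
    data.frame(
      last_visit = x$schedule$labels,
      visit_index = seq_len(J),
      arm = a,
      n_dropped = nd,
      n_evaluable = sum(sel),
      cumulative_dropout = if (sum(sel) > 0) cum / sum(sel) else
        rep(NA_real_, J)
    )
  }))
  drp$cumulative_dropout_pct <- round_half_up(drp$cumulative_dropout)
  rownames(avail) <- rownames(drp) <- NULL
  structure(list(availability = avail, dropout = drp, n = n),
            class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  cat("Score availability by visit and arm:\n")
  print(x$availability, row.names = FALSE)
  cat("\nDropout by last available visit:\n")
  print(x$dropout, row.names = FALSE)
  invisible(x)
}
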