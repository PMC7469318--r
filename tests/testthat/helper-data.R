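## shared fixtures, built in code

## small complete two-arm dataset on a short schedule
make_complete_data <- function(n_per_arm = 4, times = c(0, 1, 2, 3),
                               beta = c(50, 2, 0), seed = 1,
                               G = diag(c(4, 0.25)), sigma2 = 1) {
  set.seed(seed)
  sch <- visit_schedule(times)
  n <- 2 * n_per_arm
  arm <- rep(0:1, each = n_per_arm)
  b <- MASS::mvrnorm(n, c(0, 0), G)
  y <- beta[1] + outer(beta[2] + beta[3] * arm, times) + b[, 1] +
    outer(b[, 2], times) + matrix(rnorm(n * length(times), 0, sqrt(sigma2)),
                                  n, length(times))
  trial_data(sprintf("s%02d", seq_len(n)), arm, y, sch)
}

## dataset with a prescribed dropout-index vector
with_dropout <- function(dataset, D) {
  sc <- dataset$scores
  J <- dataset$schedule$J
  for (i in seq_along(D)) if (D[i] < J) sc[i, (D[i] + 1):J] <- NA
  trial_data(dataset$id, dataset$arm, sc, dataset$schedule)
}

## direct multivariate-normal log-density (independent oracle)
dmvnorm_log <- function(y, mu, V) {
  k <- length(y)
  as.numeric(-0.5 * (k * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       drop(t(y - mu) %*% solve(V) %*% (y - mu))))
}

## eight-visit dataset sized/shaped like the motivating trial's QL scale
make_ql_like_counts <- function() {
  ## dropout-index counts per arm chosen to reproduce the published flow:
  ## 16 experimental-arm subjects drop after baseline, 125 of 130 drop
  ## before the last visit; 89/70/58/35 across the four patterns overall
  list(
    exp = c(16, 30, 15, 20, 20, 15, 9, 5),   # sums to 130
    ctl = c(17, 26, 12, 18, 18, 14, 10, 7)   # sums to 122
  )
}

## trial_data with given per-arm dropout-count vectors (scores constant 50)
make_counts_dataset <- function(counts_exp, counts_ctl) {
  sch <- visit_schedule()
  J <- sch$J
  D <- c(rep(seq_len(J), counts_ctl), rep(seq_len(J), counts_exp))
  arm <- rep(0:1, c(sum(counts_ctl), sum(counts_exp)))
  n <- length(D)
  sc <- matrix(50, n, J)
  ds <- trial_data(sprintf("p%03d", seq_len(n)), arm, sc, sch)
  with_dropout(ds, D)
}
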