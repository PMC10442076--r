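# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (scalar loops, exhaustive scans) so they do not share
# code paths with the package implementation.

# CUSUM by direct closed form: E_n = F(n) - n * x0
oracle_cusum <- function(outcomes, x0) {
  e <- numeric(length(outcomes) + 1L)
  f <- 0
  for (n in seq_along(outcomes)) {
    f <- f + outcomes[n]
    e[n + 1L] <- f - n * x0
  }
  e
}

# endpoint by exhaustive O(N^2) suffix scan
oracle_endpoint <- function(values, tol = 1e-12) {
  e <- values[-1L]
  N <- length(e)
  if (N == 0L) return(NA_integer_)
  for (n in seq_len(N)) {
    all_below <- TRUE
    for (m in n:N) if (e[m] > tol) { all_below <- FALSE; break }
    if (all_below) return(n)
  }
  NA_integer_
}

# restricted cubic spline by the raw truncated-power formula, scalar form
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  out <- matrix(NA_real_, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    for (i in seq_along(x)) {
      cub <- function(u) if (u > 0) u^3 else 0
      out[i, j + 1L] <- (cub(x[i] - knots[j]) -
        cub(x[i] - knots[k - 1L]) * (knots[k] - knots[j]) /
          (knots[k] - knots[k - 1L]) +
        cub(x[i] - knots[k]) * (knots[k - 1L] - knots[j]) /
          (knots[k] - knots[k - 1L])) / (knots[k] - knots[1L])^2
    }
  }
  out
}

random_binary_sequence <- function(max_n = 500L) {
  n <- sample(1:max_n, 1L)
  stats::rbinom(n, 1L, stats::runif(1, 0.02, 0.5))
}

# synthetic trajectory objects following the straight-line-plus-noise model
# of the slope-homogeneity F-test (equal true slopes across operators)
noisy_linear_trajectory <- function(n, slope, intercept = 0, sd = 0.3,
                                    id = "X") {
  e <- intercept + slope * seq_len(n) + stats::rnorm(n, 0, sd)
  structure(list(values = c(0, e), x0 = 0.1, n_cases = n,
                 centre_id = id, outcome_name = "sim"),
            class = "cusum_trajectory")
}

# cohort with group-specific log-odds effects, for parameter recovery
make_group_cohort <- function(n_per_group = c(3000, 3000, 3000),
                              beta = c(0, -0.3, -2.0), intercept = -2) {
  g <- rep(1:3, n_per_group)
  p <- 1 / (1 + exp(-(intercept + beta[g])))
  data.frame(centre_id = "A",
             case_index = seq_along(g),
             experience_group = g,
             y = stats::rbinom(length(g), 1L, p))
}
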