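test_that("intercept-only logistic fit recovers the log-odds closed form", {
  y <- c(rep(1, 3), rep(0, 17))
  f <- fit_logistic(y, cbind(intercept = rep(1, 20)))
  expect_equal(unname(f$coefficients), log(3 / 17), tolerance = 1e-8)
  expect_true(f$converged)
  expect_false(f$separation)
})

test_that("aliased columns are dropped and separation is flagged", {
  set.seed(707)
  x <- rnorm(100)
  y <- rbinom(100, 1, plogis(x))
  X <- cbind(intercept = 1, x = x, x_copy = x)
  expect_warning(f <- fit_logistic(y, X), "aliased")
  expect_equal(f$dropped, "x_copy")
  expect_equal(length(f$coefficients), 2)
  # perfectly separated data (glm.fit emits its own warning too)
  ys <- as.numeric(x > 0)
  ws <- capture_warnings(fs <- fit_logistic(ys, cbind(intercept = 1, x = x)))
  expect_match(ws, "separation", all = FALSE)
  expect_true(fs$separation)
  expect_error(fit_logistic(c(0, 1, 2), cbind(1, 1:3)), "binary")
})

test_that("restricted cubic spline basis has the restricted truncated-power form", {
  knots <- c(3, 10, 20, 28)
  x <- seq(0.5, 35, length.out = 50)
  b <- rcs_basis(x, knots)
  expect_equal(ncol(b$basis), 3)   # k - 1 columns for k = 4 knots
  expect_lt(max(abs(b$basis - oracle_rcs(x, knots))), 1e-10)
  # linear beyond the outer knots: numerical second differences vanish
  for (side in list(seq(29, 40, by = 0.5), seq(-5, 2.5, by = 0.5))) {
    bb <- rcs_basis(side, knots)$basis
    d2 <- apply(bb, 2, function(col) diff(diff(col)))
    expect_lt(max(abs(d2)), 1e-8)
  }
  expect_error(rcs_basis(x, c(5, 5, 10, 20)), "strictly increasing")
  expect_error(rcs_basis(rep(1:3, 5), "auto"), "distinct")
  auto <- rcs_basis(1:100, "auto")
  expect_equal(auto$knots, unname(quantile(1:100, c(.05, .35, .65, .95))))
})

test_that("constraining the nonlinear spline coefficients to zero gives the linear deviance", {
  set.seed(808)
  n <- 400
  x <- rep(1:50, length.out = n)
  y <- rbinom(n, 1, plogis(-2 + 0.02 * x))
  cases <- data.frame(centre_id = "A", case_index = x,
                      experience_group = assign_experience_group(x), y = y)
  res <- nonlinearity_lrt(cases, "y", covariate_names = NULL)
  # deviance of the spline design evaluated at (linear coefs, 0, 0) equals
  # the linear model's deviance exactly
  co <- res$linear_fit$coefficients
  b <- rcs_basis(x, res$knots)$basis
  eta <- co["intercept"] + co["x"] * b[, 1]
  dev0 <- -2 * sum(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  expect_equal(dev0, res$linear_fit$deviance, tolerance = 1e-8)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 2)
  expect_true(all(res$curve$risk >= 0 & res$curve$risk <= 1))
  expect_true(all(res$curve$lower <= res$curve$risk + 1e-12 &
                    res$curve$risk <= res$curve$upper + 1e-12))
})

test_that("the nonlinearity test detects a strongly U-shaped risk", {
  set.seed(909)
  n <- 2000
  x <- rep(1:50, length.out = n)
  p <- plogis(-1 - 0.35 * x + 0.007 * x^2)
  cases <- data.frame(centre_id = "A", case_index = x,
                      experience_group = assign_experience_group(x),
                      y = rbinom(n, 1, p))
  res <- nonlinearity_lrt(cases, "y", covariate_names = NULL)
  expect_lt(res$p.value, 0.01)
})

test_that("adjusted group odds ratios recover simulated group effects", {
  set.seed(1010)
  cases <- make_group_cohort(n_per_group = c(4000, 4000, 4000),
                             beta = c(0, -0.3, -2.0), intercept = -2)
  res <- adjusted_group_or(cases, "y", covariate_names = NULL)
  expect_equal(res$table$or[1], 1)
  expect_lt(abs(log(res$table$or[2]) - (-0.3)), 0.2 * 0.3 + 0.1)
  expect_lt(abs(log(res$table$or[3]) - (-2.0)), 0.2 * 2.0)
  expect_true(all(res$table$lower[-1] < res$table$or[-1] &
                    res$table$or[-1] < res$table$upper[-1]))
  expect_lt(res$trend_p, 0.001)
  # a null cohort gives odds ratios near 1
  null <- make_group_cohort(beta = c(0, 0, 0))
  rn <- adjusted_group_or(null, "y", covariate_names = NULL)
  expect_true(all(rn$table$lower[-1] < 1 & 1 < rn$table$upper[-1]))
  nada <- null; nada$y <- 0L
  expect_error(adjusted_group_or(nada, "y", covariate_names = NULL),
               "no events")
})

test_that("odds-ratio intervals widen as events get rarer", {
  set.seed(1111)
  widths <- vapply(c(-1, -2, -3), function(b0) {
    cases <- make_group_cohort(n_per_group = c(2000, 2000, 2000),
                               beta = c(0, -0.2, -0.5), intercept = b0)
    t <- adjusted_group_or(cases, "y", covariate_names = NULL)$table
    log(t$upper[3]) - log(t$lower[3])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("operator interaction test is null on duplicated centres and detects divergence", {
  set.seed(1212)
  n <- 60
  one <- data.frame(centre_id = "A", case_index = 1:n,
                    experience_group = assign_experience_group(1:n),
                    y = rbinom(n, 1, 0.15))
  two <- one; two$centre_id <- "B"
  dup <- rbind(one, two)
  res <- operator_interaction_test(dup, "y")
  expect_lt(res$statistic, 1e-6)
  # one operator whose risk rises with experience instead of falling
  nn <- 400
  p_learn <- learning_curve_probability(1:nn, 0.35, 0.03, 12)
  p_rev <- 0.35 + 0.03 - p_learn          # mirrored: 0.03 rising to 0.35
  mk <- function(id, p) data.frame(centre_id = id, case_index = 1:nn,
                                   experience_group = assign_experience_group(1:nn),
                                   y = rbinom(nn, 1, p))
  big <- rbind(mk("A", p_learn), mk("B", p_learn), mk("C", p_rev))
  res2 <- operator_interaction_test(big, "y")
  expect_lt(res2$p.value, 0.01)
})
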