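fx <- build_plus_fixture()

test_that("group proportions reproduce the published table rows", {
  pm <- proportion_by_group(fx, "major_complication")
  expect_equal(pm$rates_pct, c(10.0, 7.5, 2.9))
  expect_equal(pm$pooled_pct, 5.1)
  pp <- proportion_by_group(fx, "poor_outcome")
  expect_equal(pp$rates_pct, c(7.5, 2.5, 0.7))
  expect_equal(pp$pooled_pct, 2.3)
  # zero-event cohort
  none <- fx; none$poor_outcome <- 0L
  expect_equal(proportion_by_group(none, "poor_outcome")$rates_pct, c(0, 0, 0))
  expect_error(proportion_by_group(fx, "not_a_column"), "unknown outcome")
})

test_that("display rounding is half-up to one decimal", {
  expect_equal(round_half_up(c(2.25, 2.35, -2.25), 1), c(2.3, 2.4, -2.3))
})

test_that("chi-square over groups matches the published p and degenerates correctly", {
  res <- chi_square_groups(group_table(c(4, 3, 4), c(40, 40, 137)))
  expect_equal(res$df, 2)
  expect_equal(res$p.value, 0.148, tolerance = 0.005 / 0.148)
  flat <- chi_square_groups(group_table(c(4, 4, 4), c(40, 40, 40)))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p.value, 1)
  expect_error(group_table(c(1, 0), c(10, 0)), "positive total")
})

test_that("chi-square agrees in direction with exact enumeration on tiny counts", {
  tab <- group_table(c(6, 1), c(12, 15))
  chi <- chi_square_groups(tab)
  fis <- fisher.test(rbind(c(6, 6), c(1, 14)))
  expect_lt(abs(chi$p.value - fis$p.value), 0.05)
  expect_true((chi$p.value < 0.05) == (fis$p.value < 0.05) ||
                abs(chi$p.value - fis$p.value) < 0.05)
  expect_gt(fis$estimate, 1)   # same association direction as the rates
  expect_gt(6 / 12, 1 / 15)
})

test_that("linear-by-linear trend test reproduces the published trend p-values", {
  mrs <- mantel_haenszel_trend(group_table(c(3, 1, 1), c(40, 40, 137)))
  expect_equal(mrs$df, 1)
  expect_gt(mrs$p.value, 0.010); expect_lt(mrs$p.value, 0.020)
  expect_equal(mrs$p.value, 0.0148476, tolerance = 1e-5)
  isc <- mantel_haenszel_trend(group_table(c(2, 2, 0), c(40, 40, 137)))
  expect_gt(isc$p.value, 0.010); expect_lt(isc$p.value, 0.020)
  flat <- mantel_haenszel_trend(group_table(c(4, 4, 4), c(40, 40, 40)))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p.value, 1, tolerance = 1e-12)
})

test_that("trend statistic is invariant to affine score rescaling and row permutation", {
  base <- group_table(c(3, 1, 1), c(40, 40, 137), scores = c(1, 2, 3))
  resc <- group_table(c(3, 1, 1), c(40, 40, 137), scores = c(5, 7, 9))
  expect_equal(mantel_haenszel_trend(base)$statistic,
               mantel_haenszel_trend(resc)$statistic, tolerance = 1e-12)
  expect_error(mantel_haenszel_trend(
    group_table(c(3, 1, 1), c(40, 40, 137), scores = c(2, 2, 2))), "constant")
  # counts-based computation is by construction invariant to within-group
  # row order; check it agrees with the individual-level correlation form
  x <- rep(1:3, c(40, 40, 137))
  y <- unlist(mapply(function(e, t) c(rep(1, e), rep(0, t - e)),
                     c(3, 1, 1), c(40, 40, 137)))
  m2 <- (length(y) - 1) * cor(x, y)^2
  expect_equal(mantel_haenszel_trend(base)$statistic, m2, tolerance = 1e-12)
})

test_that("Kruskal-Wallis holds size, gains power with shift, and is rank-invariant", {
  set.seed(606)
  make <- function(shift) data.frame(
    experience_group = rep(1:3, each = 30),
    v = rnorm(90) + rep(c(0, shift / 2, shift), each = 30))
  rej <- replicate(300, kruskal_wallis_groups(make(0), "v")$p.value < 0.05)
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.09)
  power <- vapply(c(0.4, 0.8, 1.2), function(s)
    mean(replicate(150, kruskal_wallis_groups(make(s), "v")$p.value < 0.05)),
    numeric(1))
  expect_true(all(diff(power) > 0))
  # rank-based: invariant to monotone transformation
  d <- make(1)
  d2 <- d; d2$v <- exp(d2$v)
  expect_equal(kruskal_wallis_groups(d, "v")$statistic,
               kruskal_wallis_groups(d2, "v")$statistic, tolerance = 1e-12)
  tied <- data.frame(experience_group = rep(1:2, each = 5), v = rep(1, 10))
  expect_warning(res <- kruskal_wallis_groups(tied, "v"), "tied")
  expect_equal(res$statistic, 0)
})

test_that("crude odds ratios match direct cross-products and invert under group swap", {
  tab <- proportion_by_group(fx, "poor_outcome")
  or31 <- crude_odds_ratio(tab, ref_group = "1", target_group = "3")
  expect_equal(or31$or, (1 * 37) / (3 * 136), tolerance = 1e-12)
  expect_equal(or31$or, 0.0907, tolerance = 1e-3 / 0.0907)
  expect_false(or31$continuity_corrected)
  or13 <- crude_odds_ratio(tab, ref_group = "3", target_group = "1")
  expect_equal(or13$or, 1 / or31$or, tolerance = 1e-12)
  equal <- group_table(c(5, 10), c(50, 100))
  expect_equal(crude_odds_ratio(equal, 1, 2)$or, 1, tolerance = 1e-12)
  zero <- group_table(c(0, 3), c(30, 30))
  cc <- crude_odds_ratio(zero, 2, 1)
  expect_true(cc$continuity_corrected)
  expect_error(crude_odds_ratio(group_table(c(0, 0), c(10, 10)), 1, 2),
               "undefined")
  expect_true(or31$lower < or31$or && or31$or < or31$upper)
})
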