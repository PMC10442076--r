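#' Construct an ordered experience-group event table
#'
#' A 2 x k summary of a binary outcome over ordered experience groups:
#' event counts and patient totals per group, with numeric trend scores
#' (default 1, 2, ..., k).
#'
#' @param events event count per group.
#' @param totals patient count per group.
#' @param labels group labels.
#' @param scores numeric trend scores per group.
#' @return an object of class `group_table`.
#' @export
#' @examples
#' group_table(events = c(4, 3, 4), totals = c(40, 40, 137))
group_table <- function(events, totals, labels = seq_along(totals),
                        scores = seq_along(totals)) {
  if (length(events) != length(totals) || length(totals) < 2L)
    stop("'events' and 'totals' must have equal length >= 2")
  if (any(totals <= 0)) stop("every group must have a positive total")
  if (any(events < 0) || any(events > totals))
    stop("'events' must satisfy 0 <= events <= totals")
  structure(list(labels = labels,
                 events = as.numeric(events),
                 totals = as.numeric(totals),
                 scores = as.numeric(scores)),
            class = "group_table")
}

#' @export
print.group_table <- function(x, ...) {
  df <- data.frame(group = x$labels, events = x$events, total = x$totals,
                   rate_pct = round_half_up(100 * x$events / x$totals, 1))
  print(df, row.names = FALSE)
  invisible(x)
}

# round half away from zero (journal-table convention), unlike base round()
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Event counts and rates by experience group
#'
#' @param cases case-level data frame carrying `experience_group` and the
#'   named binary outcome column.
#' @param outcome_name binary outcome column.
#' @return a `group_table` with additional components `rates` (full
#'   precision), `rates_pct` (percentages rounded half-up to one decimal for
#'   display), `pooled_rate` and `pooled_pct`.
#' @export
#' @examples
#' proportion_by_group(build_plus_fixture(), "major_complication")$rates_pct
proportion_by_group <- function(cases, outcome_name) {
  if (!outcome_name %in% names(cases))
    stop("unknown outcome column: ", outcome_name)
  if (!"experience_group" %in% names(cases))
    stop("cases must carry an 'experience_group' column")
  y <- cases[[outcome_name]]
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("outcome column must be binary 0/1")
  g <- factor(cases$experience_group)
  events <- tapply(y, g, sum)
  totals <- tapply(y, g, length)
  tab <- group_table(events, totals, labels = levels(g))
  tab$outcome_name <- outcome_name
  tab$rates <- tab$events / tab$totals
  tab$rates_pct <- round_half_up(100 * tab$rates, 1)
  tab$pooled_rate <- sum(tab$events) / sum(tab$totals)
  tab$pooled_pct <- round_half_up(100 * tab$pooled_rate, 1)
  tab
}

#' Pearson chi-square test over experience groups
#'
#' Tests homogeneity of the event rate across the 2 x k events/non-events
#' table, without continuity correction, on k - 1 degrees of freedom.
#'
#' @param table a [group_table()].
#' @return list with `statistic`, `df`, `p.value`.
#' @export
chi_square_groups <- function(table) {
  stopifnot(inherits(table, "group_table"))
  m <- rbind(events = table$events, nonevents = table$totals - table$events)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Mantel-Haenszel linear-by-linear trend test
#'
#' One-degree-of-freedom chi-square test for a linear association between
#' ordered group scores and a binary outcome, in the (N - 1) r^2 form: with
#' r the Pearson correlation between the group score and the individual
#' binary outcome, M^2 = (N - 1) r^2 is referred to chi-square with 1 df.
#' The statistic is invariant to affine rescaling of the scores.
#'
#' @param table a [group_table()]; its `scores` component carries the trend
#'   scores (default 1..k).
#' @return list with `statistic`, `df` (= 1), `p.value` (two-sided).
#' @export
#' @examples
#' mantel_haenszel_trend(group_table(c(3, 1, 1), c(40, 40, 137)))$p.value
mantel_haenszel_trend <- function(table) {
  stopifnot(inherits(table, "group_table"))
  sc <- table$scores
  if (length(unique(sc)) < 2L) stop("trend scores must not be constant")
  ev <- table$events; tot <- table$totals
  n <- sum(tot); e <- sum(ev)
  if (e == 0 || e == n) {
    warning("no variation in the outcome; trend statistic is 0")
    return(list(statistic = 0, df = 1L, p.value = 1))
  }
  mean_x <- sum(sc * tot) / n
  sxx <- sum(tot * sc^2) - n * mean_x^2
  syy <- e - e^2 / n                          # binary outcome sum of squares
  sxy <- sum(sc * ev) - mean_x * e
  stat <- (n - 1) * sxy^2 / (sxx * syy)
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Kruskal-Wallis comparison of a continuous variable across groups
#'
#' Rank-based H statistic with tie correction, referred to chi-square with
#' k - 1 df. When every observation is tied the statistic is 0 by
#' convention, with a warning.
#'
#' @param cases case-level data frame.
#' @param continuous_field numeric column to compare.
#' @param group_field grouping column (default `experience_group`).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
kruskal_wallis_groups <- function(cases, continuous_field,
                                  group_field = "experience_group") {
  x <- cases[[continuous_field]]
  g <- factor(cases[[group_field]])
  if (is.null(x)) stop("unknown column: ", continuous_field)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (length(unique(x)) == 1L) {
    warning("all values tied; Kruskal-Wallis statistic is 0 by convention")
    return(list(statistic = 0, df = nlevels(g) - 1L, p.value = 1))
  }
  res <- stats::kruskal.test(x, g)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Crude odds ratio between two experience groups
#'
#' Unadjusted odds ratio (target vs reference group) with the Woolf
#' log-scale 95% confidence interval. When any cell of the 2 x 2 table is
#' zero a 0.5 continuity correction is added to every cell and flagged.
#'
#' @param table a [group_table()].
#' @param ref_group,target_group group labels (as in `table$labels`).
#' @param conf_level confidence level for the Woolf interval.
#' @return list with `or`, `lower`, `upper`, `continuity_corrected`, and
#'   the 2 x 2 cell counts.
#' @export
#' @examples
#' crude_odds_ratio(group_table(c(3, 1, 1), c(40, 40, 137)), 1, 3)$or
crude_odds_ratio <- function(table, ref_group, target_group,
                             conf_level = 0.95) {
  stopifnot(inherits(table, "group_table"))
  it <- match(target_group, table$labels)
  ir <- match(ref_group, table$labels)
  if (is.na(it) || is.na(ir)) stop("unknown group label")
  a <- table$events[it]; b <- table$totals[it] - a
  cc <- table$events[ir]; d <- table$totals[ir] - cc
  if (a == 0 && cc == 0)
    stop("odds ratio undefined: no events in either group")
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       lower = exp(log(or) - z * se),
       upper = exp(log(or) + z * se),
       continuity_corrected = corrected,
       cells = c(target_events = a, target_nonevents = b,
                 ref_events = cc, ref_nonevents = d))
}
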