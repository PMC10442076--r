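#' Reference failure rate for an outcome
#'
#' The cumulative-sum chart scores each case against a fixed expected
#' failure rate X0. The defaults are the literature-derived rates used for
#' flow-diverter monitoring: 0.15 for major complications and 0.05 for poor
#' functional outcome (discharge mRS > 2). Both can be overridden by passing
#' an explicit `x0` to [cusum_trajectory()].
#'
#' @param outcome_name `"major_complication"` or `"poor_outcome"`.
#' @return the reference rate as a single numeric.
#' @export
default_reference_rate <- function(outcome_name) {
  switch(match.arg(outcome_name, c("major_complication", "poor_outcome")),
         major_complication = 0.15,
         poor_outcome = 0.05)
}

#' Cumulative-sum trajectory of observed minus expected failures
#'
#' For an ordered binary outcome sequence the CUSUM score is the recursion
#' E0 = 0, En = En-1 + (1 - x0) when case n is a failure and En-1 - x0
#' otherwise, equivalently En = F(n) - n * x0 with F(n) the cumulative
#' failure count. The chart rises when the running failure rate exceeds the
#' reference rate x0 and falls when performance is better than expected.
#'
#' @param outcomes ordered binary vector (1 = failure) in order of surgery.
#' @param x0 reference failure rate in (0, 1).
#' @param centre_id,outcome_name optional labels carried on the result.
#' @return an object of class `cusum_trajectory`: a list with `values`
#'   (E0..EN, length N + 1), `x0`, `n_cases`, `centre_id`, `outcome_name`.
#' @export
#' @examples
#' cusum_trajectory(c(0, 0, 1, 0), x0 = 0.15)$values
cusum_trajectory <- function(outcomes, x0,
                             centre_id = NA_character_,
                             outcome_name = NA_character_) {
  if (!is.numeric(x0) || length(x0) != 1L || is.na(x0) || x0 <= 0 || x0 >= 1)
    stop("'x0' must be a single rate in (0, 1)")
  outcomes <- as.numeric(outcomes)
  if (any(is.na(outcomes)) || !all(outcomes %in% c(0, 1)))
    stop("'outcomes' must be a binary (0/1) sequence with no missing values")
  structure(list(values = c(0, cumsum(outcomes - x0)),
                 x0 = x0,
                 n_cases = length(outcomes),
                 centre_id = centre_id,
                 outcome_name = outcome_name),
            class = "cusum_trajectory")
}

#' @export
print.cusum_trajectory <- function(x, ...) {
  cat(sprintf("CUSUM trajectory%s%s: N = %d, x0 = %g, E_N = %.3f\n",
              if (is.na(x$centre_id)) "" else paste0(" [", x$centre_id, "]"),
              if (is.na(x$outcome_name)) "" else paste0(" ", x$outcome_name),
              x$n_cases, x$x0, x$values[x$n_cases + 1L]))
  invisible(x)
}

#' Per-centre CUSUM trajectories for a cohort
#'
#' Splits a case-level data frame by centre, orders each centre's cases by
#' `case_index` and computes one trajectory per centre for the named
#' outcome.
#'
#' @param cases case-level data frame (see [simulate_operator_sequence()]).
#' @param outcome_name binary outcome column to chart.
#' @param x0 reference rate; defaults to [default_reference_rate()] when the
#'   outcome is one of the two standard ones.
#' @return named list of `cusum_trajectory` objects, one per centre.
#' @export
cusum_by_centre <- function(cases, outcome_name, x0 = NULL) {
  if (!outcome_name %in% names(cases))
    stop("unknown outcome column: ", outcome_name)
  if (is.null(x0)) x0 <- default_reference_rate(outcome_name)
  centres <- sort(unique(cases$centre_id))
  out <- lapply(centres, function(cc) {
    sub <- cases[cases$centre_id == cc, ]
    sub <- sub[order(sub$case_index), ]
    cusum_trajectory(sub[[outcome_name]], x0, centre_id = cc,
                     outcome_name = outcome_name)
  })
  names(out) <- centres
  out
}

#' Learning-curve endpoint of a CUSUM trajectory
#'
#' The endpoint is the first case after which the failure rate remains at
#' the expected level or lower: the smallest n >= 1 such that Em <= 0 for
#' every m from n to N. A later excursion above zero voids earlier
#' candidates; if EN > 0 no endpoint exists and `NA` is returned. Em = 0
#' counts as at the expected level. Comparisons use an absolute tolerance to
#' absorb floating-point accumulation in the recursion.
#'
#' @param traj a [cusum_trajectory()].
#' @param tol absolute tolerance for the `Em <= 0` test.
#' @return integer case index in `[1, N]`, or `NA_integer_`.
#' @export
learning_endpoint <- function(traj, tol = 1e-12) {
  stopifnot(inherits(traj, "cusum_trajectory"))
  if (traj$n_cases == 0L) return(NA_integer_)
  e <- traj$values[-1L]                      # E1..EN
  above <- which(e > tol)
  if (length(above) == 0L) return(1L)
  if (above[length(above)] == traj$n_cases) return(NA_integer_)
  above[length(above)] + 1L
}

#' Ordinary least-squares fit of the CUSUM score on case number
#'
#' Regresses En on n over n = 1..N (the E0 = 0 anchor is a boundary
#' condition, not an observation). A steadily negative slope close to -x0
#' indicates failure-free performance; slope near zero indicates performance
#' at the reference rate.
#'
#' @param traj a [cusum_trajectory()] with at least 2 cases.
#' @return list with `slope`, `intercept`, `r_squared`, `n_cases`,
#'   `centre_id`, `outcome_name`. `r_squared` is defined as 1 - SSres/SStot,
#'   taken to be 1 when SStot = 0 with zero residuals.
#' @export
fit_cusum_slope <- function(traj) {
  stopifnot(inherits(traj, "cusum_trajectory"))
  if (traj$n_cases < 2L)
    stop("at least 2 cases are required to fit a slope")
  n <- seq_len(traj$n_cases)
  e <- traj$values[-1L]
  fit <- stats::lm(e ~ n)
  ss_tot <- sum((e - mean(e))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot <= .Machine$double.eps * max(1, abs(sum(e)))) {
    if (ss_res < 1e-20) 1 else 0
  } else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2,
       n_cases = traj$n_cases,
       centre_id = traj$centre_id,
       outcome_name = traj$outcome_name)
}

#' Endpoint and slope summary over a set of trajectories
#'
#' @param trajectories list of [cusum_trajectory()] objects.
#' @return a `data.frame` with one row per trajectory (centre, endpoint,
#'   slope, intercept, R-squared, N) plus attributes `mean_endpoint` and
#'   `max_endpoint` computed over the trajectories that reached an endpoint.
#' @export
learning_curve_summary <- function(trajectories) {
  rows <- lapply(trajectories, function(tr) {
    sl <- fit_cusum_slope(tr)
    data.frame(centre_id = tr$centre_id,
               outcome_name = tr$outcome_name,
               n_cases = tr$n_cases,
               endpoint = learning_endpoint(tr),
               slope = sl$slope, intercept = sl$intercept,
               r_squared = sl$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ep <- out$endpoint[!is.na(out$endpoint)]
  attr(out, "mean_endpoint") <- if (length(ep)) mean(ep) else NA_real_
  attr(out, "max_endpoint") <- if (length(ep)) max(ep) else NA_real_
  out
}

#' Compare CUSUM slopes across operators
#'
#' Fits a pooled linear model of the CUSUM score on case number with a
#' centre main effect and a centre-by-case-number interaction, and tests
#' slope homogeneity with the F-test comparing the common-slope model
#' against the separate-slopes model.
#'
#' @param trajectories list of at least two [cusum_trajectory()] objects,
#'   each with at least 2 cases.
#' @return list with `slopes` (named per-trajectory slope vector),
#'   `statistic` (F), `df` (numerator, denominator), `p.value`.
#' @export
compare_slopes <- function(trajectories) {
  if (length(trajectories) < 2L)
    stop("at least 2 trajectories are required")
  dat <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (tr$n_cases < 2L) stop("every trajectory needs at least 2 cases")
    id <- if (is.na(tr$centre_id)) paste0("traj", i) else tr$centre_id
    data.frame(centre = id, n = seq_len(tr$n_cases),
               e = tr$values[-1L], stringsAsFactors = FALSE)
  }))
  dat$centre <- factor(dat$centre)
  fit_common <- stats::lm(e ~ centre + n, data = dat)
  fit_sep <- stats::lm(e ~ centre * n, data = dat)
  an <- stats::anova(fit_common, fit_sep)
  slopes <- vapply(trajectories, function(tr) fit_cusum_slope(tr)$slope,
                   numeric(1))
  names(slopes) <- unique(dat$centre)
  f <- an$F[2L]
  p <- an$`Pr(>F)`[2L]
  if (is.na(f) && an$`Sum of Sq`[2L] < 1e-12) { f <- 0; p <- 1 }
  list(slopes = slopes,
       statistic = f,
       df = c(an$Df[2L], an$Res.Df[2L]),
       p.value = p)
}
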