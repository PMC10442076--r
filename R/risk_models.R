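#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial-logit GLM by iteratively reweighted least squares with a
#' tight convergence tolerance (relative deviance change < 1e-10).
#' Rank-deficient designs have their aliased columns dropped with a
#' warning; quasi-separation (any fitted probability within 1e-10 of 0 or
#' 1) is detected and flagged, since Wald intervals are unreliable there.
#'
#' @param outcome binary 0/1 response vector.
#' @param design_matrix numeric model matrix including an intercept column
#'   if one is wanted.
#' @return an object of class `logistic_fit`: list with `coefficients`,
#'   `vcov`, `deviance`, `null_deviance`, `n_obs`, `converged`,
#'   `iterations`, `separation`, `dropped` (aliased column names).
#' @export
#' @examples
#' y <- c(rep(1, 3), rep(0, 17))
#' f <- fit_logistic(y, cbind(intercept = rep(1, 20)))
#' f$coefficients   # log(3/17)
fit_logistic <- function(outcome, design_matrix) {
  y <- as.numeric(outcome)
  if (any(is.na(y)) || !all(y %in% c(0, 1)))
    stop("'outcome' must be binary 0/1")
  X <- as.matrix(design_matrix)
  if (nrow(X) != length(y)) stop("design and outcome sizes differ")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping aliased columns: ", paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (length(y) <= ncol(X))
    stop("more predictors than observations")
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = list(epsilon = 1e-10, maxit = 100))
  w <- fit$weights
  xtx <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(xtx), error = function(e) matrix(NA_real_,
                 ncol(X), ncol(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  sep <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  if (sep)
    warning("quasi-separation detected; confidence intervals unreliable")
  structure(list(coefficients = stats::setNames(fit$coefficients,
                                                colnames(X)),
                 vcov = vc,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 n_obs = length(y),
                 converged = fit$converged,
                 iterations = fit$iter,
                 separation = sep,
                 dropped = dropped,
                 fitted = fit$fitted.values),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, se = se,
                   z = x$coefficients / se))
  cat(sprintf("deviance %.3f on %d obs; converged: %s\n",
              x$deviance, x$n_obs, x$converged))
  invisible(x)
}

# Adjustment design shared by the model-based operations. Two codings for
# the aneurysm covariates: "table2" uses giant (>25 mm) and posterior
# indicators; "continuous" uses size in mm and the 4-level location factor.
covariate_design <- function(cases, covariate_names,
                             coding = c("table2", "continuous")) {
  coding <- match.arg(coding)
  cols <- list()
  for (v in covariate_names) {
    if (v %in% c("age", "sex_female")) {
      cols[[v]] <- cases[[v]]
    } else if (v %in% c("operator", "centre_id")) {
      f <- factor(cases$centre_id)
      mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0("operator", levels(f)[-1L])
      cols[[v]] <- mm
    } else if (v %in% c("aneurysm_size", "aneurysm_size_mm", "giant")) {
      cols[[v]] <- if (coding == "table2")
        as.numeric(cases$aneurysm_size_mm > 25) else cases$aneurysm_size_mm
      names(cols)[length(cols)] <- if (coding == "table2") "giant" else "size_mm"
    } else if (v %in% c("location", "posterior")) {
      if (coding == "table2") {
        cols[["posterior"]] <- as.numeric(cases$location == "posterior")
      } else {
        f <- factor(cases$location)
        mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
        colnames(mm) <- paste0("location", levels(f)[-1L])
        cols[["location"]] <- mm
      }
    } else if (v %in% names(cases)) {
      cols[[v]] <- cases[[v]]
    } else stop("unknown covariate: ", v)
  }
  if (!length(cols)) return(NULL)
  out <- do.call(cbind, lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    if (is.matrix(x)) x else matrix(x, ncol = 1,
                                    dimnames = list(NULL, nm))
  }))
  out
}

default_covariates <- c("age", "sex_female", "operator",
                        "aneurysm_size", "location")

#' Covariate-adjusted odds ratios by experience group
#'
#' Multivariable logistic regression of a binary outcome on experience
#' group (group 1 as reference) adjusted for the requested covariates.
#' Wald odds ratios exp(beta) with 95% CIs exp(beta +/- 1.96 SE) are
#' reported per group, together with a trend p-value from a companion model
#' treating the group as an ordinal score.
#'
#' @param cases case-level data frame.
#' @param outcome_name binary outcome column.
#' @param covariate_names adjustment set; defaults to age, sex, operator and
#'   the aneurysm covariates.
#' @param coding `"table2"` (giant >25 mm and posterior-circulation
#'   indicators, the default) or `"continuous"` (size in mm, 4-level
#'   location).
#' @return list with `table` (data.frame: group, n, events, or, lower,
#'   upper, p), `trend_p`, `fit` (the full `logistic_fit`).
#' @export
adjusted_group_or <- function(cases, outcome_name,
                              covariate_names = default_covariates,
                              coding = c("table2", "continuous")) {
  coding <- match.arg(coding)
  y <- cases[[outcome_name]]
  if (is.null(y)) stop("unknown outcome column: ", outcome_name)
  if (sum(y) == 0) stop("no events in '", outcome_name,
                        "'; odds ratios are not estimable")
  g <- factor(cases$experience_group)
  gm <- stats::model.matrix(~g)[, -1L, drop = FALSE]
  colnames(gm) <- paste0("group", levels(g)[-1L])
  Z <- covariate_design(cases, covariate_names, coding)
  X <- cbind(intercept = 1, gm, Z)
  fit <- fit_logistic(y, X)
  idx <- match(colnames(gm), names(fit$coefficients))
  beta <- fit$coefficients[idx]
  se <- sqrt(diag(fit$vcov))[idx]
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    group = levels(g),
    n = as.vector(table(g)),
    events = as.vector(tapply(y, g, sum)),
    or = c(1, exp(beta)),
    lower = c(NA, exp(beta - z * se)),
    upper = c(NA, exp(beta + z * se)),
    p = c(NA, 2 * stats::pnorm(-abs(beta / se))),
    stringsAsFactors = FALSE)
  # ordinal-score companion model for the trend p
  Xt <- cbind(intercept = 1, score = as.numeric(cases$experience_group), Z)
  ft <- fit_logistic(y, Xt)
  bt <- ft$coefficients["score"]
  st <- sqrt(diag(ft$vcov))["score"]
  list(table = tab,
       trend_p = unname(2 * stats::pnorm(-abs(bt / st))),
       fit = fit)
}

#' Restricted cubic spline basis (Harrell parameterization)
#'
#' Truncated-power restricted cubic basis on k knots: a linear term plus
#' k - 2 nonlinear terms, each constrained so that the curve is linear
#' beyond the outer knots and normalized by (t_k - t_1)^2 so the columns
#' share the scale of x. With the default four knots the basis has exactly
#' three columns. Automatic knots sit at the 0.05, 0.35, 0.65 and 0.95
#' quantiles of x.
#'
#' @param x numeric vector (here, the within-centre case index).
#' @param knots `"auto"` or a strictly increasing numeric vector of
#'   positions (length >= 3).
#' @return object of class `rcs_basis`: list with `knots` and `basis`
#'   (matrix with columns `x`, `x'`, `x''`, ...).
#' @export
#' @examples
#' b <- rcs_basis(1:50)
#' ncol(b$basis)   # 3 columns for 4 knots
rcs_basis <- function(x, knots = "auto") {
  if (identical(knots, "auto")) {
    if (length(unique(x)) < 5L)
      stop("need >= 5 distinct x values for automatic knots")
    knots <- unname(stats::quantile(x, c(0.05, 0.35, 0.65, 0.95), type = 7))
  }
  knots <- as.numeric(knots)
  k <- length(knots)
  if (k < 3L) stop("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  pos3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1L]; t1 <- knots[1L]
  norm <- (tk - t1)^2
  basis <- matrix(x, ncol = 1)
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    col <- (pos3(x - tj) -
              pos3(x - tk1) * (tk - tj) / (tk - tk1) +
              pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
    basis <- cbind(basis, col)
  }
  colnames(basis) <- c("x", paste0("x", strrep("'", seq_len(k - 2L))))
  structure(list(knots = knots, basis = basis), class = "rcs_basis")
}

#' Likelihood-ratio test for nonlinearity of the experience effect
#'
#' Compares the adjusted logistic model with a linear case-index term
#' against the model adding the restricted-cubic-spline nonlinear terms.
#' The deviance difference is referred to chi-square with df equal to the
#' number of nonlinear terms (2 for four knots). Also exports the fitted
#' spline risk curve with a pointwise Wald band for plotting.
#'
#' @param cases case-level data frame.
#' @param outcome_name binary outcome column.
#' @param covariate_names adjustment covariates (see
#'   [adjusted_group_or()]); `NULL` for an unadjusted curve.
#' @param knots `"auto"` or explicit knot positions for [rcs_basis()].
#' @param coding aneurysm-covariate coding, as in [adjusted_group_or()].
#' @param grid_length number of points in the exported risk curve.
#' @return list with `statistic`, `df`, `p.value`, `curve` (data.frame x,
#'   risk, lower, upper at reference covariate values), `linear_fit`,
#'   `spline_fit`, `knots`.
#' @export
nonlinearity_lrt <- function(cases, outcome_name,
                             covariate_names = default_covariates,
                             knots = "auto",
                             coding = c("table2", "continuous"),
                             grid_length = 100L) {
  coding <- match.arg(coding)
  y <- cases[[outcome_name]]
  if (is.null(y)) stop("unknown outcome column: ", outcome_name)
  x <- cases$case_index
  b <- rcs_basis(x, knots)
  Z <- if (is.null(covariate_names)) NULL else
    covariate_design(cases, covariate_names, coding)
  X_lin <- cbind(intercept = 1, x = x, Z)
  X_spl <- cbind(intercept = 1, b$basis, Z)
  f_lin <- fit_logistic(y, X_lin)
  f_spl <- fit_logistic(y, X_spl)
  if (!f_lin$converged || !f_spl$converged)
    stop("nested fits did not both converge")
  df <- ncol(b$basis) - 1L
  stat <- max(0, f_lin$deviance - f_spl$deviance)
  # risk curve at reference covariates (means of the adjustment columns)
  xg <- seq(min(x), max(x), length.out = grid_length)
  bg <- rcs_basis(xg, b$knots)$basis
  zbar <- if (is.null(Z)) NULL else
    matrix(colMeans(Z), nrow = grid_length, ncol = ncol(Z), byrow = TRUE,
           dimnames = list(NULL, colnames(Z)))
  Xg <- cbind(intercept = 1, bg, zbar)
  Xg <- Xg[, names(f_spl$coefficients), drop = FALSE]
  eta <- drop(Xg %*% f_spl$coefficients)
  se <- sqrt(rowSums((Xg %*% f_spl$vcov) * Xg))
  z <- stats::qnorm(0.975)
  curve <- data.frame(x = xg,
                      risk = expit(eta),
                      lower = expit(eta - z * se),
                      upper = expit(eta + z * se))
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       curve = curve, linear_fit = f_lin, spline_fit = f_spl,
       knots = b$knots)
}

#' Sensitivity analysis: operator-by-experience interaction
#'
#' Likelihood-ratio test comparing the main-effects model (experience group
#' plus operator) against the model adding their interaction, testing
#' whether the experience effect differs between operators. Operators with
#' no events anywhere yield inestimable interaction terms; those terms are
#' dropped (via the aliasing rules of the fit) and flagged.
#'
#' @param cases case-level data frame with `experience_group` and
#'   `centre_id`.
#' @param outcome_name binary outcome column.
#' @return list with `statistic`, `df`, `p.value`, `dropped` (inestimable
#'   interaction columns).
#' @export
operator_interaction_test <- function(cases, outcome_name) {
  y <- cases[[outcome_name]]
  if (is.null(y)) stop("unknown outcome column: ", outcome_name)
  g <- factor(cases$experience_group)
  op <- factor(cases$centre_id)
  if (nlevels(op) < 2L) stop("need at least 2 operators")
  mm_main <- stats::model.matrix(~g + op)
  mm_int <- stats::model.matrix(~g * op)
  f_main <- fit_logistic(y, mm_main)
  f_int <- suppressWarnings(fit_logistic(y, mm_int))
  # aliased interaction columns are already dropped inside the fit
  df <- length(f_int$coefficients) - length(f_main$coefficients)
  stat <- max(0, f_main$deviance - f_int$deviance)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       dropped = f_int$dropped)
}
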