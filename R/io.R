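#' Analysis configuration
#'
#' Bundles the tunable settings of the pipeline: outcome column names, the
#' poor-outcome threshold (discharge mRS > 2), the CUSUM reference rates,
#' experience-group boundaries, covariate coding and the seed.
#'
#' @param x0_major,x0_poor reference failure rates for the two CUSUM
#'   charts.
#' @param group_breaks experience-group boundaries (upper edges of all
#'   groups but the last).
#' @param mrs_threshold poor outcome is `mrs_discharge > mrs_threshold`
#'   when the flag must be derived from an mRS column.
#' @param coding aneurysm-covariate coding for the adjusted models.
#' @param covariate_names adjustment set for the models.
#' @param seed integer seed used by stages that draw random numbers.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(x0_major = 0.15, x0_poor = 0.05,
                            group_breaks = c(10L, 20L),
                            mrs_threshold = 2L,
                            coding = c("table2", "continuous"),
                            covariate_names = default_covariates,
                            seed = 1L) {
  coding <- match.arg(coding)
  for (x0 in c(x0_major, x0_poor))
    if (x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)")
  if (any(group_breaks <= 0) || is.unsorted(group_breaks, strictly = TRUE))
    stop("'group_breaks' must be strictly increasing positive integers")
  structure(list(x0_major = x0_major, x0_poor = x0_poor,
                 group_breaks = as.integer(group_breaks),
                 mrs_threshold = as.integer(mrs_threshold),
                 coding = coding,
                 covariate_names = covariate_names,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

required_case_columns <- c("centre_id", "case_index")

#' Read and validate a case-level CSV
#'
#' Reads one row per patient, validates it, derives what can be derived and
#' reports what was dropped. Binary outcome columns must be 0/1; a
#' `poor_outcome` flag is derived as `mrs_discharge > 2` when only an mRS
#' column is present; `experience_group` is (re)derived from the configured
#' boundaries. Duplicate (centre, case_index) pairs are a hard error, since
#' the order of surgery must be unambiguous.
#'
#' @param path CSV file path.
#' @param config an [analysis_config()].
#' @return the validated cases `data.frame`, with a `validation_report`
#'   attribute (list: `n_read`, `n_kept`, `n_dropped`, `messages`).
#' @export
read_cases <- function(path, config = analysis_config()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_case_columns, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  msgs <- character(0)
  n_read <- nrow(raw)

  if (!"poor_outcome" %in% names(raw)) {
    if ("mrs_discharge" %in% names(raw)) {
      raw$poor_outcome <- as.integer(raw$mrs_discharge > config$mrs_threshold)
      msgs <- c(msgs, sprintf("poor_outcome derived as mrs_discharge > %d",
                              config$mrs_threshold))
    } else stop("need a 'poor_outcome' or 'mrs_discharge' column")
  }
  if (!"major_complication" %in% names(raw))
    stop("missing required column(s): major_complication")

  ok <- !is.na(raw$case_index) & raw$case_index >= 1 &
    raw$case_index == floor(raw$case_index)
  for (v in c("major_complication", "poor_outcome")) {
    bad <- !(raw[[v]] %in% c(0, 1))
    if (any(bad)) {
      msgs <- c(msgs, sprintf("%d row(s) with non-binary %s skipped",
                              sum(bad), v))
      ok <- ok & !bad
    }
  }
  if ("location" %in% names(raw)) {
    known <- c("ICA", "ACA", "MCA", "posterior")
    bad <- !is.na(raw$location) & !(raw$location %in% known)
    if (any(bad)) {
      msgs <- c(msgs, sprintf("%d row(s) with unknown location skipped",
                              sum(bad)))
      ok <- ok & !bad
    }
  }
  if (any(!ok))
    msgs <- c(msgs, sprintf("%d of %d row(s) dropped", sum(!ok), n_read))
  cases <- raw[ok, , drop = FALSE]

  key <- paste(cases$centre_id, cases$case_index)
  if (anyDuplicated(key))
    stop("duplicate (centre_id, case_index): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  cases$experience_group <- assign_experience_group(cases$case_index,
                                                    config$group_breaks)
  rownames(cases) <- NULL
  attr(cases, "validation_report") <- list(n_read = n_read,
                                           n_kept = nrow(cases),
                                           n_dropped = n_read - nrow(cases),
                                           messages = msgs)
  cases
}

#' Write a case-level CSV
#'
#' Writes the standard column order with missing covariates as empty
#' fields, so that [read_cases()] round-trips the records.
#'
#' @param cases case-level data frame.
#' @param path output path.
#' @export
write_cases <- function(cases, path) {
  lead <- intersect(c("centre_id", "case_index", "major_complication",
                      "poor_outcome", "age", "sex_female",
                      "aneurysm_size_mm", "location", "experience_group"),
                    names(cases))
  cases <- cases[, c(lead, setdiff(names(cases), lead)), drop = FALSE]
  utils::write.csv(cases, path, row.names = FALSE, na = "")
  invisible(path)
}

run_stage <- function(bundle, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    warning("stage '", name, "' failed: ", conditionMessage(e))
    structure(list(message = conditionMessage(e)), class = "failed_stage")
  })
  bundle$stages[[name]] <- if (inherits(res, "failed_stage")) "failed" else "ok"
  bundle[[name]] <- res
  bundle
}

#' Run the full learning-curve report on a cohort
#'
#' Orchestrates the pipeline on any case-level input: experience-group
#' proportions with chi-square and trend tests for both outcomes,
#' per-centre CUSUM trajectories with endpoints, slopes and the
#' slope-homogeneity test, crude and covariate-adjusted odds ratios, the
#' restricted-cubic-spline risk curve with its nonlinearity test, and the
#' operator-interaction sensitivity analysis. A failed stage is recorded in
#' the bundle and later stages still run. When `output_dir` is given, tidy
#' CSVs and a JSON run-metadata file are written.
#'
#' @param input path to a case CSV or a case-level data frame.
#' @param config an [analysis_config()].
#' @param output_dir optional directory for CSV/JSON outputs.
#' @return a report bundle (named list) invisibly containing every stage
#'   result plus `stages` (status per stage) and `config`.
#' @export
run_report <- function(input, config = analysis_config(),
                       output_dir = NULL) {
  cases <- if (is.character(input)) read_cases(input, config) else {
    input$experience_group <- assign_experience_group(input$case_index,
                                                      config$group_breaks)
    input
  }
  set.seed(config$seed)
  bundle <- list(stages = list(), config = config, n_cases = nrow(cases))
  outcomes <- c(major_complication = config$x0_major,
                poor_outcome = config$x0_poor)
  for (oc in names(outcomes)) {
    bundle <- run_stage(bundle, paste0("proportions_", oc), {
      tab <- proportion_by_group(cases, oc)
      list(table = tab,
           chi_square = chi_square_groups(tab),
           trend = mantel_haenszel_trend(tab))
    })
    bundle <- run_stage(bundle, paste0("cusum_", oc), {
      trajs <- cusum_by_centre(cases, oc, outcomes[[oc]])
      list(trajectories = trajs,
           summary = learning_curve_summary(trajs),
           slope_homogeneity = compare_slopes(trajs))
    })
    bundle <- run_stage(bundle, paste0("crude_or_", oc), {
      tab <- proportion_by_group(cases, oc)
      lapply(setdiff(tab$labels, tab$labels[1]), function(gg)
        crude_odds_ratio(tab, tab$labels[1], gg))
    })
    bundle <- run_stage(bundle, paste0("adjusted_or_", oc),
                        adjusted_group_or(cases, oc, config$covariate_names,
                                          config$coding))
    bundle <- run_stage(bundle, paste0("spline_", oc),
                        nonlinearity_lrt(cases, oc, config$covariate_names,
                                         coding = config$coding))
    bundle <- run_stage(bundle, paste0("interaction_", oc),
                        operator_interaction_test(cases, oc))
  }
  if (!is.null(output_dir)) write_report_bundle(bundle, cases, output_dir)
  invisible(bundle)
}

write_report_bundle <- function(bundle, cases, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(output_dir, ...)
  for (oc in c("major_complication", "poor_outcome")) {
    pr <- bundle[[paste0("proportions_", oc)]]
    if (!inherits(pr, "failed_stage")) {
      t <- pr$table
      utils::write.csv(data.frame(group = t$labels, events = t$events,
                                  total = t$totals, rate_pct = t$rates_pct,
                                  chi_square_p = pr$chi_square$p.value,
                                  trend_p = pr$trend$p.value),
                       fp(paste0("groups_", oc, ".csv")), row.names = FALSE)
    }
    cu <- bundle[[paste0("cusum_", oc)]]
    if (!inherits(cu, "failed_stage")) {
      traj_df <- do.call(rbind, lapply(cu$trajectories, function(tr)
        data.frame(centre_id = tr$centre_id, n = 0:tr$n_cases,
                   e_n = tr$values)))
      utils::write.csv(traj_df, fp(paste0("cusum_", oc, ".csv")),
                       row.names = FALSE)
      utils::write.csv(cu$summary, fp(paste0("cusum_summary_", oc, ".csv")),
                       row.names = FALSE)
    }
    sp <- bundle[[paste0("spline_", oc)]]
    if (!inherits(sp, "failed_stage"))
      utils::write.csv(sp$curve, fp(paste0("risk_curve_", oc, ".csv")),
                       row.names = FALSE)
    ao <- bundle[[paste0("adjusted_or_", oc)]]
    if (!inherits(ao, "failed_stage"))
      utils::write.csv(ao$table, fp(paste0("adjusted_or_", oc, ".csv")),
                       row.names = FALSE)
  }
  meta <- list(package_version = as.character(utils::packageVersion("lcurve")),
               r_version = R.version.string,
               seed = bundle$config$seed,
               config = unclass(bundle$config),
               n_cases = bundle$n_cases,
               stages = bundle$stages)
  jsonlite::write_json(meta, fp("run_metadata.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(output_dir)
}
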