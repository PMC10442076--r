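#' Assign ordinal experience groups from within-centre case order
#'
#' Consecutive procedures at a centre are binned into ordered experience
#' groups; by default cases 1-10 form group 1, cases 11-20 group 2 and all
#' later cases group 3.
#'
#' @param case_index integer vector of 1-based within-centre case order.
#' @param breaks strictly increasing positive integers giving the upper
#'   boundary of each group but the last (default `c(10, 20)`).
#' @return integer vector of group labels `1, 2, ..., length(breaks) + 1`.
#' @export
#' @examples
#' assign_experience_group(c(1, 10, 11, 20, 21, 100))
assign_experience_group <- function(case_index, breaks = c(10L, 20L)) {
  if (length(breaks) < 1L || any(breaks <= 0) || is.unsorted(breaks, strictly = TRUE))
    stop("'breaks' must be strictly increasing positive integers")
  if (any(case_index < 1 | case_index != floor(case_index), na.rm = TRUE))
    stop("'case_index' must contain positive integers")
  findInterval(case_index, breaks + 1L) + 1L
}

#' Per-case event probability under an exponential learning process
#'
#' The event probability decays from `p_start` at the first case towards the
#' plateau `p_plateau` with characteristic scale `learning_scale` (the number
#' of cases over which ~63% of the start-to-plateau gap is closed):
#' \deqn{p(n) = p_{plateau} + (p_{start} - p_{plateau}) e^{-(n-1)/s}.}
#'
#' @param n case index (vectorised), 1-based.
#' @param p_start event probability at case 1.
#' @param p_plateau asymptotic event probability.
#' @param learning_scale positive decay scale in cases.
#' @return numeric vector of probabilities.
#' @export
learning_curve_probability <- function(n, p_start, p_plateau, learning_scale) {
  stopifnot(learning_scale > 0)
  p_plateau + (p_start - p_plateau) * exp(-(n - 1) / learning_scale)
}

#' Configuration for the operator-sequence simulator
#'
#' Defaults emulate the observed multicentre cohort: four centres of 54
#' consecutive cases each; a major-complication risk decaying from 10% to
#' about 2.9% with a decay scale of 10 cases; a rarer poor-outcome risk
#' decaying from 7.5% to 0.7% with a slower scale of 15 cases; covariates
#' (age, sex, aneurysm size, location) drawn to match the cohort's marginal
#' distributions.
#'
#' @param n_centres number of operators/centres.
#' @param cases_per_centre single integer or one integer per centre.
#' @param p_start,p_plateau,learning_scale major-complication learning curve
#'   (start and plateau probabilities, decay scale in cases).
#' @param poor_p_start,poor_p_plateau,poor_learning_scale the same three
#'   parameters for the poor-outcome (discharge mRS > 2) process.
#' @param decay `"probability"` (default) applies the exponential decay on
#'   the probability scale; `"logodds"` applies it on the log-odds scale.
#' @param covariate_spec list with `age_mean`, `age_sd`, `sex_female`
#'   (fraction), `size_meanlog`, `size_sdlog` (log-normal aneurysm size in
#'   mm), `location_probs` (named probabilities over ICA/ACA/MCA/posterior).
#' @param effect_spec optional named list of per-covariate log-odds effects
#'   on both outcomes (names among `age`, `sex_female`, `aneurysm_size_mm`,
#'   `posterior`); applied as a shift on the log-odds scale.
#' @param group_breaks experience-group boundaries (see
#'   [assign_experience_group()]).
#' @param seed integer seed for the single random stream used by
#'   [simulate_operator_sequence()].
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_centres = 4L,
                              cases_per_centre = 54L,
                              p_start = 0.10, p_plateau = 0.029,
                              learning_scale = 10,
                              poor_p_start = 0.075, poor_p_plateau = 0.007,
                              poor_learning_scale = 15,
                              decay = c("probability", "logodds"),
                              covariate_spec = list(
                                age_mean = 56, age_sd = 11.2,
                                sex_female = 0.756,
                                size_meanlog = 2.533, size_sdlog = 0.505,
                                location_probs = c(ICA = 0.851, ACA = 0.018,
                                                   MCA = 0.041, posterior = 0.090)),
                              effect_spec = NULL,
                              group_breaks = c(10L, 20L),
                              seed = 1L) {
  decay <- match.arg(decay)
  if (n_centres < 1L) stop("'n_centres' must be a positive integer")
  if (length(cases_per_centre) == 1L)
    cases_per_centre <- rep(as.integer(cases_per_centre), n_centres)
  if (length(cases_per_centre) != n_centres || any(cases_per_centre < 1L))
    stop("'cases_per_centre' must be positive, length 1 or n_centres")
  for (p in c(p_start, p_plateau, poor_p_start, poor_p_plateau))
    if (is.na(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (p_plateau > p_start || poor_p_plateau > poor_p_start)
    stop("learning requires p_plateau <= p_start for both outcomes")
  if (learning_scale <= 0 || poor_learning_scale <= 0)
    stop("'learning_scale' must be positive")
  lp <- covariate_spec$location_probs
  if (abs(sum(lp) - 1) > 1e-6) stop("location_probs must sum to 1")
  structure(list(n_centres = as.integer(n_centres),
                 cases_per_centre = cases_per_centre,
                 p_start = p_start, p_plateau = p_plateau,
                 learning_scale = learning_scale,
                 poor_p_start = poor_p_start, poor_p_plateau = poor_p_plateau,
                 poor_learning_scale = poor_learning_scale,
                 decay = decay,
                 covariate_spec = covariate_spec,
                 effect_spec = effect_spec,
                 group_breaks = as.integer(group_breaks),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

# Baseline per-case probability under the configured decay model.
decay_probability <- function(n, p_start, p_plateau, scale, decay) {
  if (decay == "probability")
    learning_curve_probability(n, p_start, p_plateau, scale)
  else
    expit(logit(p_plateau) + (logit(p_start) - logit(p_plateau)) *
            exp(-(n - 1) / scale))
}

#' Simulate consecutive operator outcome sequences
#'
#' Draws per-centre sequences of independent Bernoulli outcomes whose event
#' probability decays with the within-centre case index according to the
#' configured learning process, together with patient covariates. Optional
#' covariate effects shift the baseline probability on the log-odds scale.
#' Identical configuration and seed yield identical output; centres are
#' generated in a fixed order from one seeded stream.
#'
#' @param config a [simulation_config()] object.
#' @return a `data.frame` of case records with columns `centre_id`,
#'   `case_index`, `major_complication`, `poor_outcome`, `age`, `sex_female`,
#'   `aneurysm_size_mm`, `location`, `experience_group`.
#' @export
#' @examples
#' cases <- simulate_operator_sequence(simulation_config(seed = 42))
#' table(cases$experience_group)
simulate_operator_sequence <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  cs <- config$covariate_spec
  set.seed(config$seed)
  centre_ids <- LETTERS[seq_len(config$n_centres)]
  if (config$n_centres > 26L)
    centre_ids <- sprintf("C%02d", seq_len(config$n_centres))
  out <- vector("list", config$n_centres)
  for (i in seq_len(config$n_centres)) {
    m <- config$cases_per_centre[i]
    n <- seq_len(m)
    age <- stats::rnorm(m, cs$age_mean, cs$age_sd)
    sex_female <- stats::rbinom(m, 1L, cs$sex_female)
    size <- stats::rlnorm(m, cs$size_meanlog, cs$size_sdlog)
    location <- sample(names(cs$location_probs), m, replace = TRUE,
                       prob = cs$location_probs)
    p_major <- decay_probability(n, config$p_start, config$p_plateau,
                                 config$learning_scale, config$decay)
    p_poor <- decay_probability(n, config$poor_p_start, config$poor_p_plateau,
                                config$poor_learning_scale, config$decay)
    if (!is.null(config$effect_spec)) {
      shift <- rep(0, m)
      es <- config$effect_spec
      if (!is.null(es$age)) shift <- shift + es$age * (age - cs$age_mean)
      if (!is.null(es$sex_female)) shift <- shift + es$sex_female * sex_female
      if (!is.null(es$aneurysm_size_mm))
        shift <- shift + es$aneurysm_size_mm * (size - exp(cs$size_meanlog))
      if (!is.null(es$posterior))
        shift <- shift + es$posterior * (location == "posterior")
      p_major <- expit(logit(p_major) + shift)
      p_poor <- expit(logit(p_poor) + shift)
    }
    out[[i]] <- data.frame(
      centre_id = centre_ids[i],
      case_index = n,
      major_complication = stats::rbinom(m, 1L, p_major),
      poor_outcome = stats::rbinom(m, 1L, p_poor),
      age = round(age, 1),
      sex_female = sex_female,
      aneurysm_size_mm = round(size, 1),
      location = location,
      stringsAsFactors = FALSE)
  }
  cases <- do.call(rbind, out)
  cases$experience_group <- assign_experience_group(cases$case_index,
                                                    config$group_breaks)
  rownames(cases) <- NULL
  cases
}
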