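#' Simulate one trial arm
#'
#' Draws recruitment times from the censoring model's recruitment law and
#' infection times from an exponential distribution, then applies
#' administrative censoring at study end: participant \code{i} contributes
#' \code{min(T_i, D - R_i)} person-years of surveillance and a case if
#' \code{T_i < D - R_i}. No dropout or loss to follow-up is simulated.
#'
#' @param n Number of participants (>= 0).
#' @param rate Infection rate (events per person-year, >= 0; \code{rate = 0}
#'   means no one is ever infected).
#' @param model A \code{\link{censoring_model}}.
#' @return An \code{\link{arm_summary}}.
#' @export
simulate_arm <- function(n, rate, model) {
  stopifnot(n >= 0, rate >= 0, inherits(model, "censoring_model"))
  n <- as.integer(n)
  if (n == 0L) return(structure(list(n = 0L, x = 0L, s = 0),
                                class = "arm_summary"))
  cens <- model$duration - recruitment_sample(model, n)
  tinf <- if (rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  arm_summary(n, sum(tinf < cens), sum(pmin(tinf, cens)))
}

#' Scenario configuration for the trial simulator
#'
#' Bundles the data-generating conditions of one simulation scenario: trial
#' duration, control-arm infection rate, true vaccine efficacy, recruitment/
#' censoring law, and the target expected total case count from which the
#' 1:1 per-arm sample size is derived analytically.
#'
#' @param ve True vaccine efficacy (< 1).
#' @param target_total_cases Target expected total cases across both arms.
#' @param model A \code{\link{censoring_model}} (default: uniform recruitment
#'   over the first 75\% of a 1-year trial).
#' @param lambda_c Control-arm infection rate (default 0.1 per person-year,
#'   the order observed for COVID-19 attack rates).
#' @return A list of class \code{"scenario_config"}, including the derived
#'   \code{n_control} and \code{n_vaccine}.
#' @export
scenario_config <- function(ve, target_total_cases,
                            model = censoring_model(1, "uniform", tau = 0.75),
                            lambda_c = 0.1) {
  stopifnot(ve < 1, lambda_c > 0)
  ss <- sample_size_per_arm(model, lambda_c, ve, target_total_cases)
  structure(list(ve = ve, lambda_c = lambda_c, model = model,
                 target_total_cases = target_total_cases,
                 n_control = ss$n_control, n_vaccine = ss$n_vaccine,
                 n_total = ss$n_total),
            class = "scenario_config")
}

#' Simulate a two-arm trial under a scenario
#'
#' Control arm at \code{lambda_c}, vaccine arm at
#' \code{lambda_v = (1 - ve) * lambda_c}, per-arm sizes from the analytic
#' sample-size formula. Reproducible given a seed set beforehand (or via
#' \code{seed}).
#'
#' @param scenario A \code{\link{scenario_config}}.
#' @param seed Optional integer seed.
#' @return A list of class \code{"simulated_trial"} with \code{summary} (a
#'   \code{\link{trial_summary}}), \code{true_ve}, \code{true_lambda_c} and
#'   \code{n_per_arm}.
#' @export
simulate_trial <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  ctrl <- simulate_arm(scenario$n_control, scenario$lambda_c, scenario$model)
  vacc <- simulate_arm(scenario$n_vaccine,
                       (1 - scenario$ve) * scenario$lambda_c, scenario$model)
  structure(
    list(summary = trial_summary(ctrl, vacc, scenario$model$duration),
         true_ve = scenario$ve, true_lambda_c = scenario$lambda_c,
         n_per_arm = c(control = scenario$n_control,
                       vaccine = scenario$n_vaccine)),
    class = "simulated_trial")
}
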