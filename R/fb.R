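#' Parameter point of the full-likelihood model
#'
#' The full-likelihood model is parameterised by the estimand and five
#' bounded nuisance parameters: the vaccine efficacy \code{ve} (support
#' \code{(-Inf, 1)}), the control-arm per-person infection probability
#' \code{pi_c}, and the per-person surveillance-time means and variances of
#' the two arms (\code{mu_c}, \code{sigma2_c}, \code{mu_v}, \code{sigma2_v};
#' means in \code{(0, D)}, variances in \code{(0, D^2)}). The infection rates
#' are derived: \code{lambda_c = pi_c / mu_c} and
#' \code{lambda_v = (1 - ve) * lambda_c}.
#'
#' @param ve Vaccine efficacy (< 1).
#' @param pi_c Control-arm infection probability in (0, 1).
#' @param mu_c,mu_v Mean per-person surveillance times (person-years).
#' @param sigma2_c,sigma2_v Per-person surveillance-time variances.
#' @return An object of class \code{"fb_params"}.
#' @export
fb_params <- function(ve, pi_c, mu_c, sigma2_c, mu_v, sigma2_v) {
  stopifnot(ve < 1, pi_c > 0, pi_c < 1, mu_c > 0, sigma2_c > 0,
            mu_v > 0, sigma2_v > 0)
  structure(list(ve = ve, pi_c = pi_c, mu_c = mu_c, sigma2_c = sigma2_c,
                 mu_v = mu_v, sigma2_v = sigma2_v),
            class = "fb_params")
}

#' Derived rates and covariances of a parameter point
#'
#' From the identity \code{I2 = (sigma2 + mu^2) / 2}, the per-person
#' covariance between the surveillance time and the case indicator is
#' \code{c_g = lambda_g * (sigma2_g - mu_g^2) / 2} for each arm. A point is
#' jointly valid when the vaccine-arm infection probability
#' \code{pi_v = lambda_v * mu_v} lies in (0, 1) and both conditional
#' variances \code{sigma2_g - c_g^2 / (pi_g (1 - pi_g))} are positive; the
#' sampler treats invalid points as having zero posterior density.
#'
#' @param params An \code{\link{fb_params}} point.
#' @return A list with \code{lambda_c}, \code{lambda_v}, \code{pi_v},
#'   \code{cov_c}, \code{cov_v}, \code{condvar_c}, \code{condvar_v} and a
#'   logical \code{valid}.
#' @export
fb_derive_rates <- function(params) {
  p <- params
  lambda_c <- p$pi_c / p$mu_c
  lambda_v <- (1 - p$ve) * lambda_c
  pi_v <- lambda_v * p$mu_v
  cov_c <- lambda_c * (p$sigma2_c - p$mu_c^2) / 2
  cov_v <- lambda_v * (p$sigma2_v - p$mu_v^2) / 2
  condvar_c <- p$sigma2_c - cov_c^2 / (p$pi_c * (1 - p$pi_c))
  condvar_v <- if (pi_v > 0 && pi_v < 1)
    p$sigma2_v - cov_v^2 / (pi_v * (1 - pi_v)) else NA_real_
  valid <- pi_v > 0 && pi_v < 1 && condvar_c > 0 &&
    !is.na(condvar_v) && condvar_v > 0
  list(lambda_c = lambda_c, lambda_v = lambda_v, pi_v = pi_v,
       cov_c = cov_c, cov_v = cov_v,
       condvar_c = condvar_c, condvar_v = condvar_v, valid = valid)
}

#' Full-likelihood log density of a trial summary
#'
#' The joint large-sample likelihood of the per-arm (surveillance time, case
#' count) pairs. Two algebraically linked forms are available:
#' \code{"factorized"} (the default, and the density the sampler uses) keeps
#' the exact binomial for the case count and the conditional normal for the
#' surveillance time implied by the bivariate normal approximation;
#' \code{"bivariate"} is the plain bivariate-normal density with the
#' Theorem-style covariance matrix scaled by \code{n}. They differ only in
#' the case-count margin (binomial vs normal).
#'
#' Arms with \code{n = 0} contribute nothing. Invalid parameter points
#' return \code{-Inf} rather than raising an error, so the function can be
#' used directly as an unnormalised posterior factor.
#'
#' @param trial A \code{\link{trial_summary}}.
#' @param params An \code{\link{fb_params}} point.
#' @param form \code{"factorized"} or \code{"bivariate"}.
#' @return Log density (possibly \code{-Inf}).
#' @export
fb_log_likelihood <- function(trial, params,
                              form = c("factorized", "bivariate")) {
  form <- match.arg(form)
  d <- fb_derive_rates(params)
  arm_ll <- function(arm, pi, mu, sigma2, cov) {
    if (arm$n == 0) return(0)
    if (!(pi > 0 && pi < 1)) return(-Inf)
    vtheta <- pi * (1 - pi)
    condvar <- sigma2 - cov^2 / vtheta
    if (condvar <= 0) return(-Inf)
    if (form == "factorized") {
      stats::dbinom(arm$x, arm$n, pi, log = TRUE) +
        stats::dnorm(arm$s,
                     mean = arm$n * mu + (cov / vtheta) * (arm$x - arm$n * pi),
                     sd = sqrt(arm$n * condvar), log = TRUE)
    } else {
      # bivariate normal for (s, x), mean n*(mu, pi), covariance
      # n * [sigma2, cov; cov, pi(1-pi)]
      det_n <- arm$n^2 * (sigma2 * vtheta - cov^2)
      rs <- arm$s - arm$n * mu
      rx <- arm$x - arm$n * pi
      quad <- (vtheta * rs^2 - 2 * cov * rs * rx + sigma2 * rx^2) /
        (arm$n * (sigma2 * vtheta - cov^2))
      -log(2 * pi_const) - 0.5 * log(det_n) - 0.5 * quad
    }
  }
  ll_c <- arm_ll(trial$control, params$pi_c, params$mu_c, params$sigma2_c,
                 d$cov_c)
  ll_v <- arm_ll(trial$vaccine, d$pi_v, params$mu_v, params$sigma2_v,
                 d$cov_v)
  ll_c + ll_v
}

pi_const <- base::pi

#' Default log prior of the full-likelihood model
#'
#' Bounded-support defaults: the transform \code{u = (1 - ve) / (2 - ve)}
#' (the prior conditional infection probability at equal surveillance times)
#' gets a \code{Beta(1 - ve_guess, 1)} prior, inducing a prior on VE centred
#' below the guess to avoid optimism; \code{pi_c ~ U(0, 1)};
#' \code{mu_c, mu_v ~ U(0, D)}; \code{sigma2_c, sigma2_v ~ U(0, D^2)}, all
#' independent. Returns \code{-Inf} outside the supports. The density is on
#' the natural (untransformed) scale, including the Jacobian of the
#' \code{u}-transform.
#'
#' @param params An \code{\link{fb_params}} point.
#' @param duration Trial duration \code{D} bounding the nuisance supports.
#' @param ve_guess Prior VE guess (default 0.30).
#' @return Log prior density (possibly \code{-Inf}).
#' @export
fb_log_prior <- function(params, duration, ve_guess = 0.30) {
  stopifnot(ve_guess >= 0, ve_guess < 1, duration > 0)
  p <- params
  D <- duration
  if (p$ve >= 1 || p$pi_c <= 0 || p$pi_c >= 1 ||
      p$mu_c <= 0 || p$mu_c >= D || p$sigma2_c <= 0 || p$sigma2_c >= D^2 ||
      p$mu_v <= 0 || p$mu_v >= D || p$sigma2_v <= 0 || p$sigma2_v >= D^2)
    return(-Inf)
  a0 <- 1 - ve_guess
  u <- (1 - p$ve) / (2 - p$ve)
  # Beta(a0, 1) density on u, Jacobian |du/dve| = 1/(2 - ve)^2
  lp_ve <- log(a0) + (a0 - 1) * log(u) - 2 * log(2 - p$ve)
  # uniform factors: -log(1) - 2*log(D) - 2*log(D^2)
  lp_ve - 2 * log(D) - 4 * log(D)
}

# z (unconstrained) <-> natural parameter maps used by the sampler
fb_z_to_params <- function(z, duration) {
  inv <- function(x) 1 / (1 + exp(-x))
  u <- inv(z[1])
  list(ve = (1 - 2 * u) / (1 - u), pi_c = inv(z[2]),
       mu_c = duration * inv(z[3]), sigma2_c = duration^2 * inv(z[4]),
       mu_v = duration * inv(z[5]), sigma2_v = duration^2 * inv(z[6]))
}

fb_params_to_z <- function(params, duration) {
  logit <- function(p) log(p / (1 - p))
  u <- (1 - params$ve) / (2 - params$ve)
  c(logit(u), logit(params$pi_c), logit(params$mu_c / duration),
    logit(params$sigma2_c / duration^2), logit(params$mu_v / duration),
    logit(params$sigma2_v / duration^2))
}

# unnormalised log posterior on the z scale (prior + likelihood + Jacobians),
# mirroring the compiled sampler; used for initialisation checks and tests
fb_log_post_z <- function(z, trial, ve_guess) {
  p <- fb_z_to_params(z, trial$duration)
  params <- structure(p, class = "fb_params")
  ll <- fb_log_likelihood(trial, params)
  if (!is.finite(ll)) return(-Inf)
  inv <- function(x) 1 / (1 + exp(-x))
  a0 <- 1 - ve_guess
  u <- inv(z[1])
  lp <- a0 * log(u) + log(1 - u)
  for (j in 2:6) {
    pj <- inv(z[j])
    lp <- lp + log(pj) + log(1 - pj)
  }
  ll + lp
}

#' Sampler settings for the full-likelihood posterior
#'
#' Defaults follow common practice for this model: three chains of 20000
#' iterations, burn-in 2000, thinning 10 (1800 retained draws per chain).
#'
#' @param chains Number of chains.
#' @param iterations Iterations per chain (including burn-in).
#' @param burn_in Discarded initial iterations per chain.
#' @param thin Thinning interval.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class \code{"fb_sampler_config"}.
#' @export
fb_sampler_config <- function(chains = 3, iterations = 20000,
                              burn_in = 2000, thin = 10, seed = NULL) {
  stopifnot(chains >= 1, iterations > burn_in, burn_in >= 0, thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "fb_sampler_config")
}

# data-driven starting point on the z scale, nudged into the valid region
fb_init_z <- function(trial, ve_guess) {
  D <- trial$duration
  clamp <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  arm_init <- function(arm) {
    if (arm$n == 0) return(list(pi = 0.5, mu = 0.5 * D, sigma2 = 0.25 * D^2))
    pi <- clamp(max(arm$x, 0.5) / arm$n)
    mu <- clamp(arm$s / arm$n / D) * D
    list(pi = pi, mu = mu, sigma2 = clamp((mu / D)^2 / 2 + 0.01) * D^2)
  }
  ic <- arm_init(trial$control)
  iv <- arm_init(trial$vaccine)
  ve0 <- if (trial$control$n == 0 || trial$vaccine$n == 0) ve_guess else
    1 - (iv$pi / iv$mu) / (ic$pi / ic$mu)
  u0 <- clamp((1 - ve0) / (2 - ve0))
  logit <- function(p) log(p / (1 - p))
  c(logit(u0), logit(ic$pi), logit(ic$mu / D), logit(ic$sigma2 / D^2),
    logit(iv$mu / D), logit(iv$sigma2 / D^2))
}

#' Sample the full-likelihood posterior of VE
#'
#' Runs the compiled slice-within-Gibbs sampler (univariate stepping-out
#' slice updates on logit-transformed coordinates) on the factorized
#' binomial-by-conditional-normal likelihood with the default bounded
#' priors, and summarises the posterior of VE: median point estimate,
#' equal-tailed credible bounds, split-R-hat and effective sample size.
#'
#' Identical settings (including \code{seed}) give identical draws. A
#' convergence warning (not an error) is attached when split-R-hat exceeds
#' 1.05.
#'
#' @param trial A \code{\link{trial_summary}}. Arms with \code{n = 0} are
#'   allowed and contribute no likelihood (prior-only sampling).
#' @param ve_guess Prior VE guess (default 0.30).
#' @param level Credible level (default 0.95, equal-tailed).
#' @param config An \code{\link{fb_sampler_config}}.
#' @param keep_draws Keep the full draws matrix in the result (default TRUE).
#' @return An object of class \code{"fb_posterior"}: the \code{ve_interval}
#'   fields (\code{method = "FB"}, \code{point_ve}, \code{lower_ve},
#'   \code{upper_ve}, \code{level}) plus \code{rhat}, \code{ess} and a
#'   \code{draws} data frame (\code{chain}, \code{ve}, \code{pi_c},
#'   \code{mu_c}, \code{sigma2_c}, \code{mu_v}, \code{sigma2_v}).
#' @examples
#' \donttest{
#' brazil <- trial_summary(arm_summary(1121, 8, 117),
#'                         arm_summary(1129, 1, 119), duration = 0.21)
#' fit <- fb_interval(brazil, config = fb_sampler_config(seed = 1))
#' print(fit)
#' }
#' @export
fb_interval <- function(trial, ve_guess = 0.30, level = 0.95,
                        config = fb_sampler_config(), keep_draws = TRUE) {
  stopifnot(inherits(trial, "trial_summary"), level > 0, level < 1,
            ve_guess >= 0, ve_guess < 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  z0 <- fb_init_z(trial, ve_guess)
  # overdispersed chain starts, redrawn if they land outside the valid region
  inits <- matrix(NA_real_, config$chains, 6)
  for (ch in seq_len(config$chains)) {
    z <- z0
    for (try in 1:200) {
      z <- z0 + stats::rnorm(6, 0, 0.3)
      if (is.finite(fb_log_post_z(z, trial, ve_guess))) break
      z <- z0
    }
    if (!is.finite(fb_log_post_z(z, trial, ve_guess)))
      stop("could not find a valid starting point for chain ", ch)
    inits[ch, ] <- z
  }
  raw <- fb_slice_mcmc(
    trial$control$n, trial$control$x, trial$control$s,
    trial$vaccine$n, trial$vaccine$x, trial$vaccine$s,
    trial$duration, 1 - ve_guess,
    config$iterations, config$burn_in, config$thin, inits)
  draws <- as.data.frame(raw)
  names(draws) <- c("chain", "ve", "pi_c", "mu_c", "sigma2_c", "mu_v",
                    "sigma2_v")
  alpha <- 1 - level
  qs <- stats::quantile(draws$ve, c(alpha / 2, 0.5, 1 - alpha / 2),
                        names = FALSE, type = 7)
  per_chain <- split(draws$ve, draws$chain)
  rhat <- split_rhat(per_chain)
  ess <- ess_acf(per_chain)
  if (is.finite(rhat) && rhat > 1.05)
    warning(sprintf("FB sampler split-R-hat = %.3f > 1.05; chains may not %s",
                    rhat, "have converged"))
  structure(
    list(method = "FB", point_ve = qs[2], lower_ve = qs[1], upper_ve = qs[3],
         level = level, flagged = FALSE, rhat = rhat, ess = ess,
         ve_guess = ve_guess, config = config,
         draws = if (keep_draws) draws else NULL),
    class = c("fb_posterior", "ve_interval"))
}

#' @export
print.fb_posterior <- function(x, ...) {
  cat(sprintf(
    "FB posterior: 100 x VE = %.2f (%.2f, %.2f) at level %.0f%%\n",
    100 * x$point_ve, 100 * x$lower_ve, 100 * x$upper_ve, 100 * x$level))
  cat(sprintf("  split-R-hat = %.3f, ESS = %.0f\n", x$rhat, x$ess))
  invisible(x)
}

# strip a posterior down to the plain interval container
as_ve_interval <- function(x) {
  interval_result(x$method, x$point_ve, x$lower_ve, x$upper_ve, x$level,
                  flagged = isTRUE(x$flagged))
}

# split-R-hat: each chain halved, between/within variance ratio
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    n <- length(v) %/% 2
    if (n < 2) return(NULL)
    list(v[seq_len(n)], v[(length(v) - n + 1):length(v)])
  }), recursive = FALSE)
  if (length(halves) < 2) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(v) v[seq_len(n)])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size from chain-averaged autocorrelations
# (initial positive sequence, truncated at the first small/negative lag)
ess_acf <- function(chains) {
  n <- min(lengths(chains))
  if (n < 10) return(NA_real_)
  max_lag <- min(200L, n - 2L)
  rho <- rowMeans(vapply(chains, function(v) {
    stats::acf(v[seq_len(n)], lag.max = max_lag, plot = FALSE,
               demean = TRUE)$acf[-1, 1, 1]
  }, numeric(max_lag)))
  cut <- which(rho < 0.01)
  if (length(cut)) rho <- rho[seq_len(cut[1] - 1)]
  length(chains) * n / (1 + 2 * sum(rho))
}
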