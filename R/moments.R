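#' Moment functionals of the censored exponential surveillance time
#'
#' For an exponential infection time \code{T} with rate \code{lambda} and an
#' independent administrative censoring time \code{C} with survival function
#' \code{P(C > t)}, the per-person surveillance time is \code{min(T, C)} and
#' the case indicator is \code{1(T < C)}. Their joint first and second
#' moments are governed by two integrals of the censoring survival function
#' against the exponential kernel:
#' \deqn{I_1 = \int_0^\infty e^{-\lambda t} P(C > t)\,dt, \qquad
#'       I_2 = \int_0^\infty t\,e^{-\lambda t} P(C > t)\,dt,}
#' which give \code{E[min(T,C)] = I1}, \code{E[min(T,C)^2] = 2 I2} and the
#' per-person infection probability \code{P(T < C) = lambda * I1}. These are
#' the only features of the recruitment process the joint large-sample
#' distribution of (surveillance time, case count) depends on.
#'
#' Closed forms are used for the \code{point_mass_zero} and \code{uniform}
#' families; adaptive quadrature (absolute tolerance 1e-10) otherwise. The
#' rate \code{lambda = 0} is allowed as the degenerate no-infection limit,
#' where \code{I1 = E[C]} and \code{pi = 0}.
#'
#' @param model A \code{\link{censoring_model}}.
#' @param rate Infection rate \code{lambda} in events per person-year (>= 0).
#' @return An object of class \code{"moment_set"}: a list with elements
#'   \code{rate}, \code{I1}, \code{I2}, \code{pi} (\code{= rate * I1}),
#'   \code{mu} (\code{= I1}) and \code{sigma2} (\code{= 2 I2 - I1^2}, the
#'   per-person surveillance-time variance).
#' @examples
#' m <- censoring_model(1, "uniform", tau = 0.75)
#' moment_set(m, 0.1)$pi  # per-person infection probability, about 0.0604
#' @export
moment_set <- function(model, rate) {
  stopifnot(inherits(model, "censoring_model"),
            is.numeric(rate), length(rate) == 1L)
  if (rate < 0) stop("`rate` must be non-negative")
  D <- model$duration
  if (model$family == "point_mass_zero" && rate > 0) {
    I1 <- (1 - exp(-rate * D)) / rate
    I2 <- (1 - exp(-rate * D) * (1 + rate * D)) / rate^2
  } else if (model$family == "uniform" && rate > 0) {
    cf <- uniform_moment_closed_form(D, model$tau, rate)
    I1 <- cf$I1
    I2 <- cf$I2
  } else {
    I1 <- quad_moment(model, rate, weight = function(t) 1)
    I2 <- quad_moment(model, rate, weight = function(t) t)
  }
  structure(
    list(rate = rate, I1 = I1, I2 = I2, pi = rate * I1,
         mu = I1, sigma2 = 2 * I2 - I1^2),
    class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf(
    "Surveillance-time moments at rate %g /py:\n  I1 = %.8g  I2 = %.8g  pi = %.8g  sigma2 = %.8g\n",
    x$rate, x$I1, x$I2, x$pi, x$sigma2))
  invisible(x)
}

# adaptive quadrature of weight(t) * exp(-rate t) * P(C > t) over (0, D);
# the integrand vanishes beyond D.
quad_moment <- function(model, rate, weight) {
  f <- function(t) weight(t) * exp(-rate * t) * censoring_survival(model, t)
  q <- tryCatch(
    stats::integrate(f, 0, model$duration, rel.tol = 1e-12, abs.tol = 1e-10,
                     subdivisions = 500L),
    error = function(e) stop("moment quadrature failed: ",
                             conditionMessage(e)))
  if (q$message != "OK")
    stop("moment quadrature did not converge: ", q$message)
  q$value
}

# Uniform recruitment on (0, tau*D): P(C>t) = 1 on (0, a), (D-t)/(tau*D) on
# (a, D) with a = D(1-tau). Antiderivatives of t^k exp(-lambda t) give I1, I2.
uniform_moment_closed_form <- function(D, tau, lam) {
  a <- D * (1 - tau)
  w <- tau * D
  ea <- exp(-lam * a)
  eD <- exp(-lam * D)
  I1 <- (1 - (ea - eD) / (lam * w)) / lam
  # I2 = int_0^a t e^{-lt} dt + (1/w) int_a^D t (D - t) e^{-lt} dt
  int_t_0a <- (1 - ea * (1 + lam * a)) / lam^2
  int_t_aD <- ea * (a / lam + 1 / lam^2) - eD * (D / lam + 1 / lam^2)
  int_t2_aD <- ea * (a^2 / lam + 2 * a / lam^2 + 2 / lam^3) -
    eD * (D^2 / lam + 2 * D / lam^2 + 2 / lam^3)
  I2 <- int_t_0a + (D * int_t_aD - int_t2_aD) / w
  list(I1 = I1, I2 = I2)
}

#' Per-person infection probability by direct quadrature
#'
#' Computes \code{P(T < C) = 1 - integral of exp(-lambda (D - r)) f_R(r) dr}
#' over the recruitment support, i.e. one minus the probability of escaping
#' infection over the individual follow-up window \code{D - R}. Identical, by
#' an integration-by-parts identity, to \code{moment_set(model, rate)$pi =
#' lambda * I1}; the two routes are kept separate as a numerical cross-check.
#'
#' @inheritParams moment_set
#' @return Probability in [0, 1).
#' @export
infection_prob <- function(model, rate) {
  stopifnot(inherits(model, "censoring_model"),
            is.numeric(rate), length(rate) == 1L)
  if (rate < 0) stop("`rate` must be non-negative")
  if (rate == 0) return(0)
  D <- model$duration
  if (model$family == "point_mass_zero") return(1 - exp(-rate * D))
  dens <- switch(model$family,
    uniform = function(r) rep(1 / (model$tau * D), length(r)),
    rescaled_beta22 = function(r) {
      w <- model$tau * D
      stats::dbeta(r / w, 2, 2) / w
    },
    custom = model$recruitment_density)
  q <- stats::integrate(function(r) exp(-rate * (D - r)) * dens(r),
                        0, model$tau * D, rel.tol = 1e-12, abs.tol = 1e-10)
  if (q$message != "OK")
    stop("infection probability quadrature did not converge: ", q$message)
  1 - q$value
}

#' Per-arm sample size for a target expected number of cases
#'
#' Under 1:1 allocation, the expected total case count over both arms is
#' \code{n (pi_c + pi_v)}, so the per-arm size achieving a target expected
#' total is \code{n = E[Xc + Xv] / (pi_c + pi_v)}, with the vaccine-arm
#' infection probability computed at \code{lambda_v = (1 - ve) * lambda_c}.
#'
#' The total \code{2n} is rounded half-up and split as evenly as possible
#' between the arms; the unrounded values are returned alongside, since no
#' single rounding convention reproduces every published table to better
#' than one participant.
#'
#' @param model A \code{\link{censoring_model}}.
#' @param lambda_c Control-arm infection rate (> 0).
#' @param ve True vaccine efficacy (< 1).
#' @param target_total_cases Target expected total case count (> 0).
#' @return A list with \code{n_total} (rounded total), \code{n_control},
#'   \code{n_vaccine}, \code{n_total_unrounded}, \code{per_arm_unrounded},
#'   \code{pi_c}, \code{pi_v}.
#' @examples
#' m <- censoring_model(1, "uniform", tau = 0.75)
#' sample_size_per_arm(m, lambda_c = 0.1, ve = 0.7,
#'                     target_total_cases = 900)$n_total  # 22808
#' @export
sample_size_per_arm <- function(model, lambda_c, ve, target_total_cases) {
  stopifnot(lambda_c > 0, ve < 1, target_total_cases > 0)
  pi_c <- moment_set(model, lambda_c)$pi
  pi_v <- moment_set(model, (1 - ve) * lambda_c)$pi
  if (pi_c + pi_v <= 0)
    stop("pi_c + pi_v is zero; no infections are possible under this model")
  per_arm <- target_total_cases / (pi_c + pi_v)
  total <- floor(2 * per_arm + 0.5)   # round half-up on the total
  n_c <- total %/% 2
  list(n_total = total, n_control = n_c, n_vaccine = total - n_c,
       n_total_unrounded = 2 * per_arm, per_arm_unrounded = per_arm,
       pi_c = pi_c, pi_v = pi_v)
}
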