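#' Recruitment/censoring model for a fixed-duration trial
#'
#' In a trial of fixed duration \code{D}, a participant recruited at random
#' time \code{R} is administratively censored at \code{C = D - R}. The
#' recruitment law therefore determines the censoring law, and through it the
#' moment functionals that drive both the sample-size formula and the
#' full-likelihood model. Recruitment is restricted to the first fraction
#' \code{tau} of the trial, so every participant is followed for at least
#' \code{D * (1 - tau)} years unless infected first.
#'
#' @param duration Trial duration \code{D} in years (> 0).
#' @param family Recruitment family: \code{"uniform"} (constant accrual rate
#'   on \code{(0, tau * D)}), \code{"rescaled_beta22"} (Beta(2, 2) accrual
#'   rescaled to \code{(0, tau * D)}: ramp-up then slow-down),
#'   \code{"point_mass_zero"} (everyone recruited at time 0, so \code{C == D})
#'   or \code{"custom"} (user-supplied density).
#' @param tau Accrual fraction in (0, 1]; recruitment support is
#'   \code{(0, tau * duration)}. Ignored for \code{"point_mass_zero"}.
#' @param recruitment_density For \code{family = "custom"}: a vectorised
#'   density function on \code{(0, tau * duration)}. It must integrate to 1
#'   over that interval (checked by quadrature to 1e-8).
#' @return An object of class \code{"censoring_model"}.
#' @examples
#' m <- censoring_model(duration = 1, family = "uniform", tau = 0.75)
#' censoring_survival(m, 0.625)  # P(C > 0.625) = 0.5
#' @export
censoring_model <- function(duration,
                            family = c("uniform", "rescaled_beta22",
                                       "point_mass_zero", "custom"),
                            tau = 0.75,
                            recruitment_density = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  if (family == "point_mass_zero") tau <- 0
  if (family != "point_mass_zero") {
    stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau <= 1)
  }
  if (family == "custom") {
    if (!is.function(recruitment_density))
      stop("family = 'custom' requires a `recruitment_density` function")
    total <- stats::integrate(recruitment_density, 0, tau * duration,
                              rel.tol = 1e-10, abs.tol = 1e-12)$value
    if (abs(total - 1) > 1e-8)
      stop(sprintf(
        "custom recruitment density integrates to %.10f over (0, tau*D), not 1",
        total))
  } else if (!is.null(recruitment_density)) {
    warning("`recruitment_density` ignored for family '", family, "'")
  }
  structure(
    list(duration = duration, family = family, tau = tau,
         recruitment_density = recruitment_density),
    class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  cat(sprintf("Censoring model: %s recruitment, D = %g y, tau = %g\n",
              x$family, x$duration, x$tau))
  invisible(x)
}

# CDF of the recruitment time R on [0, tau*D]; vectorised in r.
recruitment_cdf <- function(model, r) {
  D <- model$duration
  w <- model$tau * D
  r <- pmin(pmax(r, 0), w)
  switch(model$family,
    uniform = r / w,
    rescaled_beta22 = stats::pbeta(r / w, 2, 2),
    point_mass_zero = rep(1, length(r)),
    custom = vapply(r, function(ri) {
      if (ri <= 0) return(0)
      stats::integrate(model$recruitment_density, 0, ri,
                       rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1)))
}

#' Survival function of the administrative censoring time
#'
#' Returns \code{P(C > t)} where \code{C = D - R}. Equals 1 for
#' \code{t <= D * (1 - tau)} (no one can be censored before the minimum
#' follow-up) and 0 for \code{t >= D}; monotone non-increasing in between,
#' where it equals the recruitment CDF evaluated at \code{D - t}.
#'
#' @param model A \code{\link{censoring_model}}.
#' @param t Non-negative time(s) in years.
#' @return \code{P(C > t)}, vectorised over \code{t}.
#' @export
censoring_survival <- function(model, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative")
  D <- model$duration
  out <- numeric(length(t))
  lo <- t <= D * (1 - model$tau) & t < D
  out[lo] <- 1
  mid <- !lo & t < D
  if (any(mid)) out[mid] <- recruitment_cdf(model, D - t[mid])
  out
}

# Draw n recruitment times from the model's recruitment law.
recruitment_sample <- function(model, n) {
  w <- model$tau * model$duration
  switch(model$family,
    uniform = stats::runif(n, 0, w),
    rescaled_beta22 = w * stats::rbeta(n, 2, 2),
    point_mass_zero = numeric(n),
    custom = {
      # inverse-CDF by root finding; adequate for the smooth densities
      # this model accepts, and only used for simulation
      u <- stats::runif(n)
      vapply(u, function(ui) {
        stats::uniroot(function(r) recruitment_cdf(model, r) - ui,
                       lower = 0, upper = w, tol = 1e-10)$root
      }, numeric(1))
    })
}
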