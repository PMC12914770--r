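#' Conditional infection probability and its inverse
#'
#' Conditionally on the total case count, the number of vaccine-arm cases is
#' binomial with success probability
#' \deqn{\theta = \frac{s_v \lambda_v}{s_v \lambda_v + s_c \lambda_c}
#'             = \frac{s_v (1 - VE)}{s_v (1 - VE) + s_c},}
#' treating the observed surveillance times as constants. \code{theta_from_ve}
#' maps VE to \eqn{\theta}; \code{ve_from_theta} inverts it,
#' \eqn{VE = 1 - (s_c / s_v)\,\theta / (1 - \theta)}. The map is strictly
#' decreasing, so VE interval bounds come from opposite \eqn{\theta}
#' quantiles. \code{theta = 1} maps to \code{-Inf} (an unbounded-below VE).
#'
#' @param sv,sc Surveillance times (person-years, > 0) of the vaccine and
#'   control arms.
#' @param ve Vaccine efficacy (<= 1).
#' @param theta Probability in [0, 1].
#' @return A single number.
#' @export
theta_from_ve <- function(sv, sc, ve) {
  stopifnot(sv > 0, sc > 0, ve <= 1)
  sv * (1 - ve) / (sv * (1 - ve) + sc)
}

#' @rdname theta_from_ve
#' @export
ve_from_theta <- function(sv, sc, theta) {
  stopifnot(sv > 0, sc > 0, theta >= 0, theta <= 1)
  if (theta == 1) return(-Inf)
  1 - (sc / sv) * theta / (1 - theta)
}

# common container for one method's result
interval_result <- function(method, point_ve, lower_ve, upper_ve, level,
                            flagged = FALSE, ...) {
  structure(list(method = method, point_ve = point_ve, lower_ve = lower_ve,
                 upper_ve = upper_ve, level = level, flagged = flagged, ...),
            class = "ve_interval")
}

#' @export
print.ve_interval <- function(x, ...) {
  cat(sprintf("%s%s: 100 x VE = %.2f (%.2f, %.2f) at level %.0f%%\n",
              x$method, if (isTRUE(x$flagged)) " [flagged]" else "",
              100 * x$point_ve, 100 * x$lower_ve, 100 * x$upper_ve,
              100 * x$level))
  invisible(x)
}

#' @export
as.data.frame.ve_interval <- function(x, ...) {
  data.frame(method = x$method, point_ve = x$point_ve, lower_ve = x$lower_ve,
             upper_ve = x$upper_ve, level = x$level, flagged = x$flagged,
             stringsAsFactors = FALSE)
}

#' Asymptotic maximum-likelihood interval for VE
#'
#' The delta-method interval on the log incidence-rate-ratio scale:
#' \deqn{VE \in 1 - \exp\left(\log \widehat{IRR} \pm z_{1-\alpha/2}
#'   \sqrt{1/x_v + 1/x_c}\right).}
#' With a zero case count in either arm the estimator is undefined; 0.5 is
#' then substituted for the zero count in both the point estimate and the
#' variance (Haldane--Anscombe continuity correction) and the result is
#' flagged.
#'
#' @param trial A \code{\link{trial_summary}}.
#' @param level Interval level (default 0.95, equal-tailed).
#' @return A \code{ve_interval} with \code{method = "ML"}.
#' @export
ml_interval <- function(trial, level = 0.95) {
  stopifnot(level > 0, level < 1)
  xc <- trial$control$x; sc <- trial$control$s
  xv <- trial$vaccine$x; sv <- trial$vaccine$s
  flagged <- xv == 0 || xc == 0
  if (flagged) {
    xv <- xv + 0.5 * (trial$vaccine$x == 0)
    xc <- xc + 0.5 * (trial$control$x == 0)
    warning("zero case count: ML interval uses the 0.5 continuity correction")
  }
  irr <- (xv * sc) / (xc * sv)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / xv + 1 / xc)
  interval_result("ML",
                  point_ve = 1 - irr,
                  lower_ve = 1 - exp(log(irr) + z * se),
                  upper_ve = 1 - exp(log(irr) - z * se),
                  level = level, flagged = flagged)
}

#' Conditional Bayesian credible interval for VE
#'
#' The conjugate beta-binomial interval conditional on the total case count.
#' The prior on \eqn{\theta} is \code{Beta(a0, 1)} with
#' \code{a0 = theta0 / (1 - theta0) = 1 - ve_guess}, where
#' \code{theta0 = (1 - ve_guess) / (2 - ve_guess)} is the prior conditional
#' infection probability at equal surveillance times; the second shape
#' parameter is fixed at 1 for maximal prior spread without bimodality. The
#' posterior is \code{Beta(a0 + xv, 1 + xc)}; equal-tailed beta quantiles are
#' transformed to the VE scale through the observed surveillance-time ratio,
#' and the point estimate is the transformed posterior median.
#'
#' \code{cb_interval_improper} is the improper-prior variant: posterior
#' \code{Beta(xv, xc)}, requiring at least one case in each arm.
#'
#' @param trial A \code{\link{trial_summary}}.
#' @param ve_guess Conservative prior guess of VE (default 0.30).
#' @param level Interval level (default 0.95, equal-tailed).
#' @return A \code{ve_interval} with \code{method = "CB"} (or
#'   \code{"CB_improper"}).
#' @examples
#' polack <- trial_summary(arm_summary(17511, 162, 2222),
#'                         arm_summary(17411, 8, 2214), duration = 0.21)
#' cb_interval(polack)  # 94.83 (90.32, 97.62) on the 100 x VE scale
#' @export
cb_interval <- function(trial, ve_guess = 0.30, level = 0.95) {
  stopifnot(level > 0, level < 1, ve_guess >= 0, ve_guess < 1)
  a0 <- 1 - ve_guess   # theta0/(1-theta0) with theta0 = (1-g)/(2-g)
  beta_theta_interval(trial, shape1 = a0 + trial$vaccine$x,
                      shape2 = 1 + trial$control$x,
                      method = "CB", level = level)
}

#' @rdname cb_interval
#' @export
cb_interval_improper <- function(trial, level = 0.95) {
  stopifnot(level > 0, level < 1)
  xv <- trial$vaccine$x; xc <- trial$control$x
  if (xv < 1 || xc < 1)
    stop("improper-prior posterior is undefined with a zero case count")
  beta_theta_interval(trial, shape1 = xv, shape2 = xc,
                      method = "CB_improper", level = level)
}

# equal-tailed beta posterior on theta, transformed to the VE scale;
# point = transformed posterior median
beta_theta_interval <- function(trial, shape1, shape2, method, level) {
  sv <- trial$vaccine$s; sc <- trial$control$s
  alpha <- 1 - level
  q <- stats::qbeta(c(alpha / 2, 0.5, 1 - alpha / 2), shape1, shape2)
  interval_result(method,
                  point_ve = ve_from_theta(sv, sc, q[2]),
                  lower_ve = ve_from_theta(sv, sc, q[3]),
                  upper_ve = ve_from_theta(sv, sc, q[1]),
                  level = level)
}

#' Clopper--Pearson exact interval for VE
#'
#' The exact binomial confidence interval on \eqn{\theta} given the total
#' case count, \eqn{\theta_{lo} = Beta_{\alpha/2}(x_v, 1 + x_c)} and
#' \eqn{\theta_{hi} = Beta_{1-\alpha/2}(1 + x_v, x_c)} (0 and 1 respectively
#' when the corresponding count is zero), transformed to the VE scale. The
#' point estimate is the plug-in \code{1 - IRR}.
#'
#' @inheritParams cb_interval
#' @return A \code{ve_interval} with \code{method = "CP"}.
#' @export
cp_interval <- function(trial, level = 0.95) {
  stopifnot(level > 0, level < 1)
  xv <- trial$vaccine$x; xc <- trial$control$x
  if (xv + xc < 1) stop("Clopper-Pearson interval requires at least one case")
  sv <- trial$vaccine$s; sc <- trial$control$s
  alpha <- 1 - level
  theta_lo <- if (xv == 0) 0 else stats::qbeta(alpha / 2, xv, 1 + xc)
  theta_hi <- if (xc == 0) 1 else stats::qbeta(1 - alpha / 2, 1 + xv, xc)
  point <- if (xc == 0) NA_real_ else ve_point(trial)
  interval_result("CP",
                  point_ve = point,
                  lower_ve = ve_from_theta(sv, sc, theta_hi),
                  upper_ve = ve_from_theta(sv, sc, theta_lo),
                  level = level)
}

#' All interval methods for one trial
#'
#' Convenience wrapper running any subset of the methods and returning a
#' single data frame (one row per method).
#'
#' @param trial A \code{\link{trial_summary}}.
#' @param methods Character vector among \code{"ml"}, \code{"cb"},
#'   \code{"cb_improper"}, \code{"cp"}, \code{"fb"}.
#' @param level Interval level.
#' @param ve_guess Prior VE guess for the Bayesian methods.
#' @param ... Passed to \code{\link{fb_interval}} (sampler settings) when
#'   \code{"fb"} is requested.
#' @return A data frame with columns \code{method}, \code{point_ve},
#'   \code{lower_ve}, \code{upper_ve}, \code{level}, \code{flagged}.
#' @export
ve_intervals <- function(trial, methods = c("ml", "cb", "cp"),
                         level = 0.95, ve_guess = 0.30, ...) {
  methods <- match.arg(methods, c("ml", "cb", "cb_improper", "cp", "fb"),
                       several.ok = TRUE)
  rows <- lapply(methods, function(m) {
    res <- switch(m,
      ml = ml_interval(trial, level = level),
      cb = cb_interval(trial, ve_guess = ve_guess, level = level),
      cb_improper = cb_interval_improper(trial, level = level),
      cp = cp_interval(trial, level = level),
      fb = as_ve_interval(fb_interval(trial, ve_guess = ve_guess,
                                      level = level, ...)))
    as.data.frame(res)
  })
  do.call(rbind, rows)
}
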