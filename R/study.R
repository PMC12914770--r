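#' Empirical coverage of a set of intervals
#'
#' Fraction (as a percentage) of intervals containing the true VE, with the
#' binomial Monte-Carlo standard error
#' \code{100 * sqrt(p (1 - p) / reps)}.
#'
#' @param intervals A data frame with columns \code{lower_ve} and
#'   \code{upper_ve} (one row per replicate).
#' @param true_ve True vaccine efficacy.
#' @return A list with \code{coverage} (percent) and \code{mcse}.
#' @export
coverage <- function(intervals, true_ve) {
  stopifnot(is.data.frame(intervals),
            all(c("lower_ve", "upper_ve") %in% names(intervals)))
  if (nrow(intervals) == 0L) stop("no intervals supplied")
  hit <- intervals$lower_ve <= true_ve & true_ve <= intervals$upper_ve
  p <- mean(hit)
  list(coverage = 100 * p,
       mcse = 100 * sqrt(p * (1 - p) / length(hit)))
}

#' Average percentage width reduction of one method vs another
#'
#' The per-replicate convention (default): mean over replicates of
#' \code{100 * (W_other - W_ref) / W_other}, where \code{W} is the interval
#' width \code{upper_ve - lower_ve}. The ratio-of-means alternative
#' \code{100 * (1 - mean(W_ref) / mean(W_other))} is available via
#' \code{convention}; at the scales studied here the two differ by well
#' under one percentage point. Replicates with a zero-width or non-finite
#' competitor interval are excluded and counted.
#'
#' @param ref Data frame of the reference method's intervals (the one whose
#'   narrowness is being quantified), columns \code{lower_ve},
#'   \code{upper_ve}.
#' @param other Paired data frame of the competitor's intervals.
#' @param convention \code{"per_replicate"} or \code{"ratio_of_means"}.
#' @return A list with \code{reduction} (percent), \code{mcse} (per-replicate
#'   convention only) and \code{n_excluded}.
#' @export
width_reduction <- function(ref, other,
                            convention = c("per_replicate",
                                           "ratio_of_means")) {
  convention <- match.arg(convention)
  stopifnot(nrow(ref) == nrow(other), nrow(ref) > 0)
  w_ref <- ref$upper_ve - ref$lower_ve
  w_other <- other$upper_ve - other$lower_ve
  ok <- is.finite(w_ref) & is.finite(w_other) & w_other > 0
  if (convention == "per_replicate") {
    r <- 100 * (w_other[ok] - w_ref[ok]) / w_other[ok]
    list(reduction = mean(r),
         mcse = stats::sd(r) / sqrt(length(r)),
         n_excluded = sum(!ok))
  } else {
    list(reduction = 100 * (1 - mean(w_ref[ok]) / mean(w_other[ok])),
         mcse = NA_real_, n_excluded = sum(!ok))
  }
}

#' Run one simulation scenario of the coverage/width study
#'
#' Simulates \code{reps} trials under the scenario, computes the requested
#' intervals for each, and aggregates empirical coverage (with MCSE), mean
#' interval width, and -- when \code{"fb"} is among the methods -- the
#' average percentage width reduction of FB against each competitor.
#'
#' Because the FB interval needs MCMC while the others are closed-form, FB
#' can be evaluated on only the first \code{fb_reps} replicates; coverage and
#' width comparisons involving FB then use that subset (paired). Replicates
#' where a zero case count forces the continuity-corrected ML interval are
#' counted in \code{n_flagged} but retained.
#'
#' @param scenario A \code{\link{scenario_config}}.
#' @param methods Subset of \code{c("fb", "cb", "cp", "ml")}.
#' @param reps Number of simulated trials for the closed-form methods.
#' @param fb_reps Number of replicates on which FB is evaluated (defaults to
#'   \code{reps}; capped at \code{reps}).
#' @param fb_config An \code{\link{fb_sampler_config}} for the FB runs
#'   (scaled-down chains are the default here; full-length chains cost about
#'   an order of magnitude more).
#' @param ve_guess Prior VE guess for the Bayesian methods.
#' @param level Interval level.
#' @param seed Optional integer seed for the whole scenario.
#' @return A list of class \code{"study_result"}: \code{scenario},
#'   \code{n_replicates}, \code{fb_reps}, \code{n_flagged}, and per-method
#'   \code{coverage}, \code{mcse}, \code{mean_width}, plus
#'   \code{width_reduction_vs} when FB was run.
#' @export
run_scenario <- function(scenario, methods = c("cb", "cp", "ml"),
                         reps = 1000, fb_reps = NULL,
                         fb_config = fb_sampler_config(chains = 3,
                                                       iterations = 6000,
                                                       burn_in = 1000,
                                                       thin = 5),
                         ve_guess = 0.30, level = 0.95, seed = NULL) {
  methods <- match.arg(methods, c("fb", "cb", "cp", "ml"), several.ok = TRUE)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  run_fb <- "fb" %in% methods
  fb_reps <- if (run_fb) min(if (is.null(fb_reps)) reps else fb_reps, reps)
             else 0L
  empty <- data.frame(lower_ve = numeric(reps), upper_ve = numeric(reps))
  res <- list(cb = empty, cp = empty, ml = empty,
              fb = if (run_fb) empty[seq_len(fb_reps), , drop = FALSE])
  n_flagged <- 0L
  for (i in seq_len(reps)) {
    trial <- simulate_trial(scenario)$summary
    if (trial$control$x == 0L || trial$vaccine$x == 0L)
      n_flagged <- n_flagged + 1L
    if ("cb" %in% methods) {
      ci <- cb_interval(trial, ve_guess = ve_guess, level = level)
      res$cb[i, ] <- c(ci$lower_ve, ci$upper_ve)
    }
    if ("cp" %in% methods) {
      ci <- if (trial$control$x + trial$vaccine$x >= 1L)
        cp_interval(trial, level = level)
      else list(lower_ve = NA_real_, upper_ve = NA_real_)
      res$cp[i, ] <- c(ci$lower_ve, ci$upper_ve)
    }
    if ("ml" %in% methods) {
      ci <- suppressWarnings(ml_interval(trial, level = level))
      res$ml[i, ] <- c(ci$lower_ve, ci$upper_ve)
    }
    if (run_fb && i <= fb_reps) {
      fit <- fb_interval(trial, ve_guess = ve_guess, level = level,
                         config = fb_config, keep_draws = FALSE)
      res$fb[i, ] <- c(fit$lower_ve, fit$upper_ve)
    }
  }
  out <- list(scenario = scenario, n_replicates = reps, fb_reps = fb_reps,
              n_flagged = n_flagged, methods = methods,
              coverage = list(), mcse = list(), mean_width = list(),
              width_reduction_vs = list())
  for (m in methods) {
    df <- res[[m]]
    cov <- coverage(df[stats::complete.cases(df), , drop = FALSE],
                    scenario$ve)
    out$coverage[[m]] <- cov$coverage
    out$mcse[[m]] <- cov$mcse
    out$mean_width[[m]] <- mean(df$upper_ve - df$lower_ve, na.rm = TRUE)
  }
  if (run_fb) {
    for (m in setdiff(methods, "fb")) {
      out$width_reduction_vs[[m]] <-
        width_reduction(res$fb, res[[m]][seq_len(fb_reps), , drop = FALSE])
    }
  }
  class(out) <- "study_result"
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "Scenario: VE = %g, %s recruitment, E[cases] = %g, n_total = %d, reps = %d\n",
    x$scenario$ve, x$scenario$model$family, x$scenario$target_total_cases,
    x$scenario$n_total, x$n_replicates))
  for (m in x$methods)
    cat(sprintf("  %-3s coverage %.1f%% (MCSE %.2f), mean width %.4f\n",
                toupper(m), x$coverage[[m]], x$mcse[[m]], x$mean_width[[m]]))
  for (m in names(x$width_reduction_vs))
    cat(sprintf("  FB width reduction vs %s: %.2f%%\n", toupper(m),
                x$width_reduction_vs[[m]]$reduction))
  invisible(x)
}
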