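#' Observed summary of one trial arm
#'
#' The sufficient data for every interval method in this package: the number
#' of participants, the number of infections, and the total surveillance time
#' (person-years at risk, summed over participants up to infection or
#' administrative censoring).
#'
#' @param n Participant count (> 0, integer).
#' @param x Case count (integer, 0 <= x <= n).
#' @param s Total surveillance time in person-years (> 0).
#' @return An object of class \code{"arm_summary"}.
#' @export
arm_summary <- function(n, x, s) {
  stopifnot(length(n) == 1L, length(x) == 1L, length(s) == 1L,
            is.finite(n), is.finite(x), is.finite(s))
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer")
  if (x < 0 || x > n || x != round(x))
    stop("`x` must be an integer in [0, n]")
  if (s < 0 || (n > 0 && s <= 0)) stop("`s` must be positive")
  structure(list(n = as.integer(round(n)), x = as.integer(round(x)), s = s),
            class = "arm_summary")
}

#' Observed summary of a two-arm vaccine trial
#'
#' @param control,vaccine \code{\link{arm_summary}} objects, or lists with
#'   elements \code{n}, \code{x}, \code{s}.
#' @param duration Trial duration \code{D} in years (> 0). Used by the
#'   full-likelihood model to bound the nuisance parameters; per-person
#'   surveillance cannot exceed \code{D}.
#' @param label Optional free-text label.
#' @return An object of class \code{"trial_summary"}.
#' @examples
#' brazil <- trial_summary(control = arm_summary(1121, 8, 117),
#'                         vaccine = arm_summary(1129, 1, 119),
#'                         duration = 0.21, label = "Brazil")
#' ve_point(brazil)
#' @export
trial_summary <- function(control, vaccine, duration, label = "") {
  as_arm <- function(a) {
    if (inherits(a, "arm_summary")) a else arm_summary(a$n, a$x, a$s)
  }
  control <- as_arm(control)
  vaccine <- as_arm(vaccine)
  stopifnot(length(duration) == 1L, is.finite(duration), duration > 0)
  for (a in list(control, vaccine)) {
    if (a$s > a$n * duration + 1e-8)
      stop("surveillance time exceeds n * duration for one arm")
  }
  structure(list(control = control, vaccine = vaccine,
                 duration = duration, label = as.character(label)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial%s (D = %g y)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$duration))
  cat(sprintf("  control: n = %d, cases = %d, surveillance = %g py\n",
              x$control$n, x$control$x, x$control$s))
  cat(sprintf("  vaccine: n = %d, cases = %d, surveillance = %g py\n",
              x$vaccine$n, x$vaccine$x, x$vaccine$s))
  invisible(x)
}

#' Maximum-likelihood point estimates from a trial summary
#'
#' \code{irr_point} returns the ML estimate of the incidence rate ratio,
#' \code{(xv / sv) / (xc / sc)}; \code{ve_point} returns \code{1 - IRR}.
#'
#' @param trial A \code{\link{trial_summary}}.
#' @return A single number.
#' @export
irr_point <- function(trial) {
  c_ <- trial$control; v <- trial$vaccine
  if (c_$x == 0) stop("IRR estimate undefined: zero cases in the control arm")
  if (v$s <= 0) stop("IRR estimate undefined: zero vaccine surveillance time")
  (v$x * c_$s) / (c_$x * v$s)
}

#' @rdname irr_point
#' @export
ve_point <- function(trial) 1 - irr_point(trial)

#' Read trial summaries from CSV or JSON
#'
#' Expects a CSV with header \code{label,nc,xc,sc,nv,xv,sv,D} or a JSON array
#' of objects with those fields.
#'
#' @param path File path; extension selects the parser (\code{.json} vs CSV).
#' @return A list of \code{\link{trial_summary}} objects.
#' @export
load_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("no trial records in ", path)
    return(list())
  }
  needed <- c("label", "nc", "xc", "sc", "nv", "xv", "sv", "D")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing columns in ", path, ": ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    tryCatch(
      trial_summary(control = arm_summary(row$nc, row$xc, row$sc),
                    vaccine = arm_summary(row$nv, row$xv, row$sv),
                    duration = row$D, label = row$label),
      error = function(e) stop(sprintf("%s line %d: %s", path, i + 1L,
                                       conditionMessage(e)), call. = FALSE))
  })
}

#' The Pfizer/BioNTech COVID-19 trial summaries
#'
#' The six published population/subgroup summaries of the 2020--2021
#' Pfizer/BioNTech COVID-19 vaccine trial (overall populations at the
#' November 2020 and March 2021 cut-offs, plus the male, Hispanic or Latinx,
#' over-65 and Brazil subgroups), shipped as a packaged fixture. Surveillance
#' times are in 1000 person-years as published; the duration at risk is the
#' accrual-start to cut-off interval minus 28 days (participants count as at
#' risk from 7 days after the second dose, given 21 days after
#' randomisation), expressed in years.
#'
#' @return A list of six \code{\link{trial_summary}} objects.
#' @examples
#' trials <- pfizer_trials()
#' ve_point(trials[["Brazil"]])
#' @export
pfizer_trials <- function() {
  path <- system.file("extdata", "pfizer_table3.csv", package = "vebayes",
                      mustWork = TRUE)
  trials <- load_trials(path)
  names(trials) <- vapply(trials, `[[`, character(1), "label")
  trials
}

#' Write interval or study results to CSV or JSON
#'
#' Full numeric precision is preserved; use \code{\link{format_ve_table}} for
#' a display table rounded to two decimals on the 100 x VE scale.
#'
#' @param results A data frame of results.
#' @param path Output path; extension selects the format (\code{.json} vs CSV).
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(results, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(results, path, row.names = FALSE)
  }
  invisible(path)
}

#' Display table on the 100 x VE scale
#'
#' Rounds point estimates and bounds half-up to two decimals on the
#' 100 x VE scale, the convention used when publishing VE estimates.
#'
#' @param results A data frame with columns \code{point_ve}, \code{lower_ve},
#'   \code{upper_ve} on the VE (0--1) scale.
#' @return A data frame with character columns \code{estimate} and
#'   \code{interval}, plus any identifying columns of the input.
#' @export
format_ve_table <- function(results) {
  r2 <- function(v) sprintf("%.2f", floor(100 * v * 100 + 0.5) / 100)
  keep <- setdiff(names(results),
                  c("point_ve", "lower_ve", "upper_ve", "level"))
  out <- results[keep]
  out$estimate <- r2(results$point_ve)
  out$interval <- paste0("(", r2(results$lower_ve), ", ",
                         r2(results$upper_ve), ")")
  out
}
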