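# Published trial rows used across tests (built in code so tests do not
# depend on the installed fixture except where the fixture itself is tested).
table3_trials <- function() {
  mk <- function(nc, xc, sc, nv, xv, sv, D, label)
    trial_summary(arm_summary(nc, xc, sc), arm_summary(nv, xv, sv), D, label)
  list(
    thomas = mk(20713, 850, 6003, 20712, 77, 6247, 0.55, "Overall March 2021"),
    polack = mk(17511, 162, 2222, 17411, 8, 2214, 0.21, "Overall Nov. 2020"),
    male   = mk(8762, 81, 1108, 8875, 3, 1124, 0.21, "Male"),
    hisp   = mk(4746, 53, 600, 4764, 3, 605, 0.21, "Hispanic or Latinx"),
    over65 = mk(3880, 19, 511, 3848, 1, 508, 0.21, "Over 65"),
    brazil = mk(1121, 8, 117, 1129, 1, 119, 0.21, "Brazil"))
}

# Independent Monte-Carlo oracle for the surveillance-time moments: draws
# recruitment and infection times directly (not via package code) and
# returns empirical moments with standard errors.
mc_moments_oracle <- function(family, D, tau, rate, n_draws) {
  r <- switch(family,
              uniform = stats::runif(n_draws, 0, tau * D),
              rescaled_beta22 = tau * D * stats::rbeta(n_draws, 2, 2),
              point_mass_zero = numeric(n_draws))
  cens <- D - r
  tinf <- if (rate > 0) stats::rexp(n_draws, rate) else rep(Inf, n_draws)
  m <- pmin(tinf, cens)
  hit <- as.numeric(tinf < cens)
  list(mean_min = mean(m), se_mean = stats::sd(m) / sqrt(n_draws),
       second_moment = mean(m^2),
       se_second = stats::sd(m^2) / sqrt(n_draws),
       p_case = mean(hit), se_case = stats::sd(hit) / sqrt(n_draws))
}

# interval data frame from a ve_interval, for study helpers
iv_df <- function(...) {
  rows <- lapply(list(...), function(x)
    data.frame(lower_ve = x$lower_ve, upper_ve = x$upper_ve))
  do.call(rbind, rows)
}
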