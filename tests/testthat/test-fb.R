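test_that("derived rates follow the moment identities", {
  p <- fb_params(ve = 0, pi_c = 0.06, mu_c = 0.8, sigma2_c = 0.5,
                 mu_v = 0.8, sigma2_v = 0.5)
  d <- fb_derive_rates(p)
  # ve = 0 with identical nuisances: the two arms are exchangeable
  expect_equal(d$lambda_v, d$lambda_c)
  expect_equal(d$pi_v, p$pi_c, tolerance = 1e-12)
  expect_equal(d$cov_v, d$cov_c)
  expect_equal(d$lambda_c, 0.06 / 0.8)
  # cov = lambda (sigma2 - mu^2)/2, i.e. lambda I2 - lambda mu^2 with
  # I2 = (sigma2 + mu^2)/2
  lam <- 0.06 / 0.8
  expect_equal(d$cov_c, lam * ((0.5 + 0.8^2) / 2 - 0.8^2), tolerance = 1e-12)
  expect_true(d$valid)
  # pi_c / mu_c division as stated
  p2 <- fb_params(0.5, pi_c = 0.06, mu_c = 0.94, sigma2_c = 0.6,
                  mu_v = 0.94, sigma2_v = 0.6)
  expect_equal(fb_derive_rates(p2)$lambda_c, 0.06 / 0.94, tolerance = 1e-9)
})

test_that("derived rates round-trip through the moments engine", {
  # pi and mu computed from a censoring model at a known rate must invert
  # back to that rate, and the implied pi_v must match the vaccine-arm
  # moments at lambda_v
  m <- censoring_model(1, "uniform", tau = 0.75)
  lam_c <- 0.0638
  ve <- 0.4
  ms_c <- moment_set(m, lam_c)
  ms_v <- moment_set(m, (1 - ve) * lam_c)
  p <- fb_params(ve, pi_c = ms_c$pi, mu_c = ms_c$mu, sigma2_c = ms_c$sigma2,
                 mu_v = ms_v$mu, sigma2_v = ms_v$sigma2)
  d <- fb_derive_rates(p)
  expect_equal(d$lambda_c, lam_c, tolerance = 1e-9)
  expect_equal(d$pi_v, ms_v$pi, tolerance = 1e-9)
  expect_true(d$valid)
})

test_that("invalid parameter points get zero likelihood, not errors", {
  tr <- table3_trials()$brazil
  # pi_v = (1 - ve) * (pi_c / mu_c) * mu_v > 1
  bad <- fb_params(-60, pi_c = 0.5, mu_c = 0.1, sigma2_c = 0.02,
                   mu_v = 0.2, sigma2_v = 0.02)
  expect_identical(fb_log_likelihood(tr, bad), -Inf)
  ok <- fb_params(0.8, pi_c = 0.007, mu_c = 0.104, sigma2_c = 0.0055,
                  mu_v = 0.105, sigma2_v = 0.0056)
  expect_true(is.finite(fb_log_likelihood(tr, ok)))
})

test_that("zero surveillance-case covariance separates the likelihood", {
  tr <- table3_trials()$brazil
  # sigma2 = mu^2 makes cov = 0: binomial + independent normal
  p <- fb_params(0.8, pi_c = 0.007, mu_c = 0.104, sigma2_c = 0.104^2,
                 mu_v = 0.105, sigma2_v = 0.105^2)
  d <- fb_derive_rates(p)
  by_hand <-
    dbinom(8, 1121, 0.007, log = TRUE) +
    dnorm(117, 1121 * 0.104, sqrt(1121 * 0.104^2), log = TRUE) +
    dbinom(1, 1129, d$pi_v, log = TRUE) +
    dnorm(119, 1129 * 0.105, sqrt(1129 * 0.105^2), log = TRUE)
  expect_equal(fb_log_likelihood(tr, p), by_hand, tolerance = 1e-10)
})

test_that("factorized and bivariate forms differ only in the case margin", {
  # one-armed trials isolate each arm; replacing the exact binomial margin
  # with its normal approximation must recover the bivariate density exactly
  arms <- list(
    list(tr = trial_summary(arm_summary(1121, 8, 117), arm_summary(0, 0, 0),
                            0.21),
         n = 1121, x = 8,
         p = fb_params(0.5, pi_c = 0.0072, mu_c = 0.105, sigma2_c = 0.006,
                       mu_v = 0.1, sigma2_v = 0.005),
         margin = function(p, d) c(p$pi_c, p$pi_c)),
    list(tr = trial_summary(arm_summary(0, 0, 0), arm_summary(1129, 1, 119),
                            0.21),
         n = 1129, x = 1,
         p = fb_params(0.5, pi_c = 0.0072, mu_c = 0.105, sigma2_c = 0.006,
                       mu_v = 0.1, sigma2_v = 0.005),
         margin = NULL))
  for (a in arms) {
    d <- fb_derive_rates(a$p)
    pi_g <- if (is.null(a$margin)) d$pi_v else a$p$pi_c
    fact <- fb_log_likelihood(a$tr, a$p, form = "factorized")
    biv <- fb_log_likelihood(a$tr, a$p, form = "bivariate")
    swapped <- fact -
      dbinom(a$x, a$n, pi_g, log = TRUE) +
      dnorm(a$x, a$n * pi_g, sqrt(a$n * pi_g * (1 - pi_g)), log = TRUE)
    expect_equal(swapped, biv, tolerance = 1e-10)
  }
})

test_that("default log prior matches its closed form and supports", {
  p <- fb_params(0.5, 0.3, 0.4, 0.2, 0.4, 0.2)
  # D = 1: uniform constants vanish; u = 1/3
  u <- 1 / 3
  expected <- log(0.7) + (0.7 - 1) * log(u) - 2 * log(1.5)
  expect_equal(fb_log_prior(p, duration = 1, ve_guess = 0.3), expected,
               tolerance = 1e-12)
  # outside the nuisance boxes
  out <- fb_params(0.5, 0.3, 0.4, 0.2, 0.4, 0.2)
  out$mu_v <- 1.5
  expect_identical(fb_log_prior(out, duration = 1), -Inf)
  # duration scaling: uniform priors contribute -6 log D
  expect_equal(fb_log_prior(p, duration = 2) - fb_log_prior(p, duration = 1),
               -6 * log(2), tolerance = 1e-12)
})

test_that("the sampler is deterministic given a seed", {
  tr <- table3_trials()$brazil
  cfg <- fb_sampler_config(chains = 2, iterations = 1500, burn_in = 300,
                           thin = 5, seed = 314)
  a <- fb_interval(tr, config = cfg)
  b <- fb_interval(tr, config = cfg)
  expect_identical(a$draws, b$draws)
  expect_identical(a$point_ve, b$point_ve)
  c_ <- fb_interval(tr, config = fb_sampler_config(chains = 2,
                                                   iterations = 1500,
                                                   burn_in = 300, thin = 5,
                                                   seed = 315))
  expect_false(identical(a$point_ve, c_$point_ve))
})

test_that("posterior draws respect the parameter supports", {
  tr <- table3_trials()$over65
  f <- fb_interval(tr, config = fb_sampler_config(chains = 2,
                                                  iterations = 3000,
                                                  burn_in = 500, thin = 5,
                                                  seed = 8))
  d <- f$draws
  D <- tr$duration
  expect_true(all(d$ve < 1))
  expect_true(all(d$pi_c > 0 & d$pi_c < 1))
  expect_true(all(d$mu_c > 0 & d$mu_c < D & d$mu_v > 0 & d$mu_v < D))
  expect_true(all(d$sigma2_c > 0 & d$sigma2_c < D^2 &
                  d$sigma2_v > 0 & d$sigma2_v < D^2))
  # every retained point is jointly valid
  lam_v <- (1 - d$ve) * d$pi_c / d$mu_c
  expect_true(all(lam_v * d$mu_v > 0 & lam_v * d$mu_v < 1))
  expect_true(is.finite(f$rhat))
  expect_true(f$ess > 100)
})

test_that("a data-free run reproduces the closed-form prior on VE", {
  # with both arms empty the likelihood is constant, so VE draws follow the
  # prior: u ~ Beta(0.7, 1) with CDF u^0.7, mapped through ve = (1-2u)/(1-u)
  tr <- trial_summary(arm_summary(0, 0, 0), arm_summary(0, 0, 0), 1)
  f <- fb_interval(tr, ve_guess = 0.3,
                   config = fb_sampler_config(chains = 3, iterations = 22000,
                                              burn_in = 2000, thin = 2,
                                              seed = 27))
  u_q <- function(p) p^(1 / 0.7)
  ve_of_u <- function(u) (1 - 2 * u) / (1 - u)
  # tolerances are ~4 Monte-Carlo standard errors at 30000 draws, from the
  # delta method on the Beta(0.7, 1) quantile density (the 2.5% VE quantile
  # sits in the heavy left tail, hence the wide band)
  expect_equal(f$point_ve, ve_of_u(u_q(0.5)), tolerance = 0.06)
  expect_equal(f$lower_ve, ve_of_u(u_q(0.975)), tolerance = 0.15)
  expect_equal(f$upper_ve, ve_of_u(u_q(0.025)), tolerance = 0.01)
})

test_that("prior guess washes out under large counts", {
  tr <- table3_trials()$thomas
  cfg <- function(s) fb_sampler_config(chains = 2, iterations = 6000,
                                       burn_in = 1000, thin = 2, seed = s)
  pts <- sapply(c(0, 0.3, 0.7), function(g)
    fb_interval(tr, ve_guess = g, config = cfg(5))$point_ve)
  expect_lt(max(pts) - min(pts), 0.003)
})

test_that("R-side and compiled posteriors agree (log-density consistency)", {
  # the R reference log posterior must be finite and maximal near the chain's
  # own high-density draws, and -Inf exactly where the sampler never goes
  tr <- table3_trials()$brazil
  f <- fb_interval(tr, config = fb_sampler_config(chains = 1,
                                                  iterations = 2000,
                                                  burn_in = 400, thin = 10,
                                                  seed = 99))
  d <- f$draws
  lps <- vapply(seq_len(nrow(d)), function(i) {
    p <- fb_params(d$ve[i], d$pi_c[i], d$mu_c[i], d$sigma2_c[i], d$mu_v[i],
                   d$sigma2_v[i])
    fb_log_likelihood(tr, p) + fb_log_prior(p, tr$duration)
  }, numeric(1))
  expect_true(all(is.finite(lps)))
})
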