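# shared simulator: binary exposure, Gaussian mediator, Gompertz survival
sim_med <- function(n, alpha, bx, bm, seed, p_x = 0.4) {
  set.seed(seed)
  x <- rbinom(n, 1, p_x)
  m <- alpha * x + rnorm(n)
  tr <- simulate_survival(bx * x + bm * m, list(a = 0.09, b = 0.004),
                          censor_years = 8, seed = seed + 1)
  dplyr::bind_cols(tr, tibble::tibble(x = x, m = m))
}

test_that("mediator model recovers the exposure shift and yields unit null weights", {
  d <- sim_med(2000, 0, 0.5, 0.3, 1)
  mm <- fit_mediator_model(d, "m", "x")
  co <- summary(mm$fit)$coefficients
  expect_lt(abs(co["x", 1]), 2 * co["x", 2])
  d2 <- sim_med(2000, 0.5, 0, 0.5, 2)
  mm2 <- fit_mediator_model(d2, "m", "x")
  expect_lt(abs(coef(mm2$fit)[["x"]] - 0.5),
            2 * summary(mm2$fit)$coefficients["x", 2])
  dz <- d; dz$m <- dz$x  # deterministic mediator
  expect_error(fit_mediator_model(dz, "m", "x"), "variance")
})

test_that("density-ratio weights favor mediator values typical of the counterfactual", {
  # hand case: m|x=0 ~ N(0,1), m|x=1 ~ N(1,1); subject with X=0
  # reweighted to x* = 1 gets larger weight at m = 1 than at m = 3
  d <- sim_med(4000, 1, 0, 0.3, 3)
  mm <- fit_mediator_model(d, "m", "x")
  dens <- function(m_obs, x_obs, x_star) {
    nd <- tibble::tibble(m = m_obs, x = x_obs)
    mu_star <- predict(mm$fit, newdata = transform(nd, x = x_star))
    mu_obs <- predict(mm$fit, newdata = nd)
    dnorm(m_obs, mu_star, mm$sigma) / dnorm(m_obs, mu_obs, mm$sigma)
  }
  w_center <- dens(coef(mm$fit)[1] + coef(mm$fit)[2], 0, 1)
  w_tail <- dens(coef(mm$fit)[1] - 4, 0, 1)
  expect_gt(w_center, w_tail)
})

test_that("natural-effects decomposition is exact on the log scale", {
  d <- sim_med(1500, 0.4, 0.3, 0.3, 4)
  est <- natural_effects_cox(d, "x", "m")
  expect_equal(est$log_hr[est$effect == "te"],
               est$log_hr[est$effect == "nde"] +
                 est$log_hr[est$effect == "nie"], tolerance = 1e-12)
  expect_true(all(est$hr > 0))
  expect_error(natural_effects_cox(dplyr::mutate(d, x = x * 0L), "x", "m"))
})

test_that("null-mediation and full-mediation generators are recovered", {
  # no exposure -> mediator path: NIE ~ 1, proportion mediated ~ 0
  nie <- pm <- numeric(8)
  for (s in 1:8) {
    d <- sim_med(2000, 0, 0.6, 0.3, 100 + s)
    est <- natural_effects_cox(d, "x", "m")
    nie[s] <- est$hr[est$effect == "nie"]
    pm[s] <- est$proportion_mediated[est$effect == "te"]
  }
  expect_gt(mean(nie), 0.95); expect_lt(mean(nie), 1.05)
  expect_lt(abs(mean(pm)), 0.1)

  # exposure acts only through the mediator: NDE ~ 1, proportion > 0.8
  nde <- pm2 <- numeric(8)
  for (s in 1:8) {
    d <- sim_med(3000, 0.8, 0, 0.5, 200 + s)
    est <- natural_effects_cox(d, "x", "m")
    nde[s] <- est$hr[est$effect == "nde"]
    pm2[s] <- est$proportion_mediated[est$effect == "te"]
  }
  expect_lt(abs(mean(log(nde))), 0.1)
  expect_gt(mean(pm2), 0.8)
})

test_that("proportion mediated follows the log-HR ratio formula", {
  expect_equal(proportion_mediated(1.08, 2.47), log(1.08) / log(2.47),
               tolerance = 1e-12)
  expect_equal(round(proportion_mediated(1.08, 2.47), 2), 0.09)  # ~8-9%
  expect_equal(proportion_mediated(1, 2), 0)
  expect_equal(proportion_mediated(1.7, 1.7), 1)
  expect_warning(out <- proportion_mediated(1.1, 1), "undefined")
  expect_true(is.na(out))
})

test_that("bootstrap CIs are seeded, honest about failures, and match an oracle", {
  set.seed(5)
  d <- tibble::tibble(v = rnorm(60, 10, 2))
  const_est <- function(dd) c(k = 42)
  ci0 <- bootstrap_ci(const_est, d, n_boot = 50, seed = 1)
  expect_equal(unname(ci0$ci_low), 42)
  expect_equal(unname(ci0$ci_high), 42)

  mean_est <- function(dd) c(mu = mean(dd$v))
  ci <- bootstrap_ci(mean_est, d, n_boot = 400, seed = 7)
  # independent oracle replaying the same per-replicate seed policy
  reps <- vapply(1:400, function(r) {
    set.seed(rhythmage:::derive_seed(7, r))
    mean(d$v[sample.int(60, 60, replace = TRUE)])
  }, 0)
  expect_equal(unname(ci$ci_low), unname(quantile(reps, 0.025, type = 7)),
               tolerance = 1e-12)
  expect_equal(unname(ci$ci_high), unname(quantile(reps, 0.975, type = 7)),
               tolerance = 1e-12)
  expect_identical(bootstrap_ci(mean_est, d, n_boot = 50, seed = 3),
                   bootstrap_ci(mean_est, d, n_boot = 50, seed = 3))

  flaky <- function(dd) if (any(duplicated(dd$v))) stop("boom") else c(s = 1)
  expect_error(bootstrap_ci(flaky, d, n_boot = 50, seed = 2), "failed")
})

test_that("sex-stratified mediation handles symmetric and single-sex cohorts", {
  mk <- function(n, seed, sexes = c("male", "female")) {
    set.seed(seed)
    d <- sim_med(n, 0.5, 0.3, 0.4, seed)
    d$sex <- sample(sexes, n, replace = TRUE)
    d$cosinor_amplitude <- rnorm(n, 40, 10) - 5 * d$x
    d$interdaily_stability <- runif(n, 0.2, 0.8)
    d$mvpa_hours <- rlnorm(n, log(0.5), 0.6)
    d$sii_z <- d$m
    d
  }
  d <- mk(1200, 11)
  res <- suppressWarnings(
    sex_stratified_mediation(d, mediator = "sii_z", covariates = character(),
                             n_boot = 0))
  expect_setequal(unique(res$exposure),
                  c("irregularity", "insufficient_mvpa", "low_amplitude"))
  expect_setequal(unique(res$sex), c("male", "female"))
  expect_equal(nrow(res), 2 * 3 * 3)

  solo <- suppressWarnings(
    sex_stratified_mediation(mk(700, 12, "male"), mediator = "sii_z",
                             covariates = character(), n_boot = 0))
  expect_setequal(unique(solo$sex), "male")
  expect_equal(nrow(solo), 9)
})

test_that("the parametric Gompertz engine agrees with the Cox engine", {
  d <- sim_med(1200, 0.4, 0.4, 0.3, 21)
  a <- natural_effects_cox(d, "x", "m")
  g <- natural_effects_cox(d, "x", "m", engine = "gompertz")
  expect_equal(g$log_hr, a$log_hr, tolerance = 0.02)
  expect_equal(g$log_hr[g$effect == "te"],
               g$log_hr[g$effect == "nde"] + g$log_hr[g$effect == "nie"],
               tolerance = 1e-12)
})
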