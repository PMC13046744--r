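test_that("log-likelihood matches a hand-evaluated three-subject toy", {
  # printed toy set: times, events, linear predictors
  tt <- c(2, 5, 7); dd <- c(1, 0, 1); eta <- c(0.3, -0.1, 0)
  a <- 0.08; b <- 0.004
  by_hand <- 0
  for (i in 1:3) {
    H <- (b / a) * (exp(a * tt[i]) - 1) * exp(eta[i])
    by_hand <- by_hand + dd[i] * (log(b) + a * tt[i] + eta[i]) - H
  }
  expect_equal(gompertz_loglik(a, b, eta, tt, dd), by_hand, tolerance = 1e-10)
  # exponential limit is continuous at a = 0
  expect_equal(gompertz_loglik(0, b, eta, tt, dd),
               gompertz_loglik(1e-10, b, eta, tt, dd), tolerance = 1e-8)
})

test_that("exponential special case reproduces the closed-form MLE", {
  tr <- simulate_survival(rep(0, 500), list(a = 0, b = 0.1),
                          censor_years = 1e9, seed = 12)
  f <- fit_gompertz_ph(tr, character(), shape = 0)
  expect_equal(f$b, sum(tr$event) / sum(tr$time), tolerance = 1e-8)
  expect_true(f$shared_shape)
})

test_that("Gompertz PH recovers simulated parameters", {
  set.seed(77)
  n <- 4000
  amp <- rnorm(n, 40, 15)
  tr <- simulate_survival(-0.02 * (amp - 40), list(a = 0.09, b = exp(-9)),
                          censor_years = 1e6, seed = 13)
  d <- dplyr::bind_cols(tr, tibble::tibble(amp_c = amp - 40))
  f <- fit_gompertz_ph(d, "amp_c")
  expect_lt(f$grad_norm, 1e-8)
  expect_equal(f$a, 0.09, tolerance = 0.1)
  expect_equal(f$log_b, -9, tolerance = 0.04)
  se <- sqrt(diag(f$vcov))["amp_c"]
  expect_lt(abs(f$coefficients[["amp_c"]] - (-0.02)),
            0.05 * 0.02 + 2 * se)

  expect_error(fit_gompertz_ph(dplyr::mutate(d, event = 0), "amp_c"),
               "no events")
  expect_error(fit_gompertz_ph(dplyr::mutate(d, time = time - 10), "amp_c"),
               "> 0")
})

test_that("biological age equals chronological age under the null model", {
  mk_model <- function(coeffs, covs) {
    structure(list(a = 0.09, b = 3e-5, log_b = log(3e-5),
                   coefficients = coeffs, covariates = covs, horizon = 5,
                   shared_shape = FALSE, vcov = NULL),
              class = "gompertz_ph")
  }
  full <- mk_model(c(amp = 0, age = 0.085), c("amp", "age"))
  only <- mk_model(c(age = 0.085), "age")
  set.seed(4)
  d <- tibble::tibble(subject_id = sprintf("s%03d", 1:200),
                      amp = rnorm(200, 40, 10), age = runif(200, 40, 70))
  res <- cosinor_age(full, only, d)
  expect_lt(max(abs(res$ba - res$ca)), 1e-10)
  expect_equal(res$aa, res$ba - res$ca)
  expect_identical(res$accelerated, res$aa > 0)

  # closed form equals a bisection root of the risk equality, and the
  # plugged-in BA reproduces the full-model 5-year cumulative hazard
  full2 <- mk_model(c(amp = -0.02, age = 0.08), c("amp", "age"))
  full2$a <- 0.11
  res2 <- cosinor_age(full2, only, d)
  g0 <- function(a, t) if (abs(a) < 1e-8) t else expm1(a * t) / a
  h_full <- full2$b * g0(full2$a, 5) *
    exp(as.matrix(d[, c("amp", "age")]) %*% full2$coefficients)
  h_only_at <- function(ba) only$b * g0(only$a, 5) * exp(0.085 * ba)
  expect_lt(max(abs(h_only_at(res2$ba) - h_full)), 1e-10)
  for (i in c(1, 50, 200)) {
    root <- stats::uniroot(function(ba) h_only_at(ba) - h_full[i],
                           c(-200, 400), tol = 1e-12)$root
    expect_equal(res2$ba[i], root, tolerance = 1e-8)
  }

  # BA strictly increasing in the linear predictor and in CA
  ord <- order(h_full)
  expect_true(all(diff(res2$ba[ord]) > 0))
  d2 <- d; d2$age <- d$age + 1
  expect_true(all(cosinor_age(full2, only, d2)$ba > res2$ba))

  only_bad <- mk_model(c(age = -0.01), "age")
  expect_error(cosinor_age(full2, only_bad, d), "> 0")
})

test_that("BA 60 vs CA 55 is five years accelerated", {
  mk_model <- function(coeffs, covs, b) {
    structure(list(a = 0.09, b = b, log_b = log(b), coefficients = coeffs,
                   covariates = covs, horizon = 5, shared_shape = FALSE),
              class = "gompertz_ph")
  }
  only <- mk_model(c(age = 0.09), "age", 3e-5)
  # full model whose linear predictor forces BA = 60 for a 55-year-old
  full <- mk_model(c(age = 0.09, shiftvar = 0.09 * 5), c("age", "shiftvar"),
                   3e-5)
  d <- tibble::tibble(age = 55, shiftvar = 1)
  res <- cosinor_age(full, only, d)
  expect_equal(res$ba, 60, tolerance = 1e-10)
  expect_equal(res$aa, 5, tolerance = 1e-10)
  expect_true(res$accelerated)
})

test_that("lower-amplitude subjects show higher mean age acceleration", {
  co <- shared_cohort()
  fe <- cohort_features(co)
  d <- dplyr::inner_join(fe, co$covariates, by = "subject_id")
  # models at the generator's protective-amplitude truth
  mk_model <- function(coeffs, covs) {
    structure(list(a = 0.09, b = 3e-5, log_b = log(3e-5),
                   coefficients = coeffs, covariates = covs, horizon = 5,
                   shared_shape = FALSE), class = "gompertz_ph")
  }
  full <- mk_model(c(cosinor_amplitude = -0.02, age = 0.09),
                   c("cosinor_amplitude", "age"))
  only <- mk_model(c(age = 0.09), "age")
  res <- cosinor_age(full, only, d)
  lo <- d$cosinor_amplitude < median(d$cosinor_amplitude)
  expect_gt(mean(res$aa[lo]), mean(res$aa[!lo]))
})

test_that("age-acceleration strata use the printed right-closed bins", {
  expect_equal(as.character(aa_stratum(c(0, 5, -5, -3, 3, 5.01, -5.2))),
               c("-3<AA<=0", "3<AA<=5", "AA<=-5", "-5<AA<=-3", "0<AA<=3",
                 "AA>5", "AA<=-5"))
  d <- tibble::tibble(aa = c(-6, -4, -1, 1, 4, 7, 2),
                      mvpa = c(1.2, 1.0, 0.9, 0.8, 0.6, 0.4, 0.7),
                      sex = c("f", "f", "m", "m", "f", "m", "m"))
  out <- stratify_age_acceleration(d, "mvpa")
  expect_equal(out$median_mvpa[out$.stratum == "0<AA<=3"],
               median(c(0.8, 0.7)))
  out2 <- stratify_age_acceleration(d, "mvpa", by = "sex")
  expect_true(all(c(".stratum", "sex", "n", "median_mvpa") %in% names(out2)))
})

test_that("externally supplied coefficient sets plug into the age solver", {
  full <- gompertz_model(0.09, 3e-5, c(cosinor_amplitude = -0.02, age = 0.09))
  only <- gompertz_model(0.09, 3e-5, c(age = 0.09))
  d <- tibble::tibble(cosinor_amplitude = c(30, 50), age = c(60, 60))
  res <- cosinor_age(full, only, d)
  # the lower-amplitude subject is biologically older
  expect_gt(res$ba[1], res$ba[2])
  expect_equal(res$ca, c(60, 60))
})

test_that("case weights reproduce duplicated-data Gompertz fits", {
  tr <- simulate_survival(rep(0, 400), list(a = 0.08, b = 0.01),
                          censor_years = 30, seed = 31)
  d <- dplyr::bind_cols(tr, tibble::tibble(z = rnorm(400)))
  f_w <- fit_gompertz_ph(d, "z", weights = rep(2, 400))
  f_d <- fit_gompertz_ph(dplyr::bind_rows(d, d), "z")
  expect_equal(f_w$coefficients, f_d$coefficients, tolerance = 1e-6)
  expect_equal(f_w$a, f_d$a, tolerance = 1e-6)
})
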