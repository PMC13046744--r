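test_that("ENMO from raw acceleration follows the clipping rule", {
  mk_raw <- function(z) tibble::tibble(t_s = seq(0, 119.9, by = 0.1),
                                       x_g = 0, y_g = 0, z_g = z)
  expect_equal(enmo_from_raw(mk_raw(1))$enmo_mg, c(0, 0))
  expect_equal(enmo_from_raw(mk_raw(1.2))$enmo_mg, c(200, 200),
               tolerance = 1e-10)
  expect_equal(enmo_from_raw(mk_raw(0.8))$enmo_mg, c(0, 0))  # negatives zeroed
  expect_error(enmo_from_raw(mk_raw(1)[0, ]), "empty")
})

test_that("wear QC enforces total hours and diurnal coverage", {
  full <- mk_cosinor(40, 20, 14, days = 7)
  expect_true(qc_wear(full)$pass)

  short <- full[1:(60 * 60), ]                       # 60 h of wear
  r <- qc_wear(short)
  expect_false(r$pass)
  expect_match(r$reason, "insufficient")

  gap <- full
  hod <- as.integer(format(gap$timestamp, "%H", tz = "UTC"))
  gap$wear[hod == 3] <- FALSE                  # 03:00-04:00 never worn
  r2 <- qc_wear(gap)
  expect_false(r2$pass)
  expect_match(r2$reason, "hour-of-day")
})

test_that("noise-free cosinor parameters are recovered essentially exactly", {
  s <- mk_cosinor(50, 20, 14, days = 3)
  f <- fit_cosinor(s)
  expect_equal(f$mesor, 50, tolerance = 1e-6)
  expect_equal(f$amplitude, 20, tolerance = 1e-6)
  expect_equal(f$acrophase, 14, tolerance = 1e-6)
  expect_equal(f$up_mesor, 8, tolerance = 1e-6)
  expect_true(f$pseudo_f > 1e6)

  td <- tidy(f)
  expect_equal(td$estimate[td$term == "amplitude"], 20, tolerance = 1e-6)

  const <- mk_series(rep(50, 3 * 1440))
  f0 <- fit_cosinor(const)
  expect_equal(f0$mesor, 50)
  expect_equal(f0$amplitude, 0)
  expect_false(f0$acrophase_defined)
  expect_equal(f0$pseudo_f, 0)

  expect_error(fit_cosinor(s[1:100, ]), "insufficient")
})

test_that("the linearized fit agrees with a brute-force phase-grid oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- mk_cosinor(50, 20, runif(1, 0, 24), days = 3, noise_sd = 25)
    f <- fit_cosinor(s)
    o <- cosinor_grid_oracle(s, res = 0.01)
    expect_equal(f$amplitude, o$amplitude, tolerance = 0.02)
    d <- abs(f$acrophase - o$acrophase)
    expect_lt(min(d, 24 - d), 0.011)
    expect_lte(f$rss, o$sse * (1 + 1e-9))  # OLS can't lose to the grid
  }
})

test_that("period search finds a non-24-h rhythm", {
  t <- (seq_len(5 * 1440) - 1) / 60
  s <- mk_series(50 + 20 * cos(2 * pi * (t - 14) / 24.6))
  f <- fit_cosinor(s, period_search = TRUE)
  expect_equal(f$period, 24.6, tolerance = 1e-3)
  expect_equal(f$amplitude, 20, tolerance = 1e-3)
})

test_that("day-level CV follows the population-SD definition", {
  # three days with amplitudes 40, 50, 60, no noise
  t <- (seq_len(3 * 1440) - 1) / 60
  amp <- c(40, 50, 60)[floor(t / 24) + 1]
  s <- mk_series(100 + amp * cos(2 * pi * (t - 14) / 24))
  cv <- daily_cosinor_cv(s)
  expect_equal(cv$amplitude_cv, 100 * sqrt(200 / 3) / 50, tolerance = 1e-6)
  expect_equal(cv$amplitude_cv, 16.33, tolerance = 1e-3)
  expect_equal(cv$acrophase_cv, 0, tolerance = 1e-6)
  daily <- attr(cv, "daily")
  expect_equal(daily$amplitude, c(40, 50, 60), tolerance = 1e-6)

  # identical days: all CVs zero
  s2 <- mk_cosinor(50, 20, 14, days = 4)
  cv2 <- daily_cosinor_cv(s2)
  expect_equal(cv2$amplitude_cv, 0, tolerance = 1e-8)

  # too few valid days: NA sentinel with a warning
  expect_warning(out <- daily_cosinor_cv(mk_cosinor(50, 20, 14, days = 2)),
                 "valid day")
  expect_true(is.na(out$amplitude_cv))
})

test_that("circular CV unwraps acrophases near midnight", {
  # daily acrophases 23.5, 0.5 (= 24.5 unwrapped), 23.8: tight cluster
  t <- (seq_len(3 * 1440) - 1) / 60
  ac <- c(23.5, 24.5, 23.8)[floor(t / 24) + 1]
  s <- mk_series(50 + 20 * cos(2 * pi * (t - ac) / 24))
  cv <- daily_cosinor_cv(s)
  vals <- c(23.5, 24.5, 23.8)
  expect_equal(cv$acrophase_cv,
               100 * sqrt(mean((vals - mean(vals))^2)) / mean(vals),
               tolerance = 1e-3)
})

test_that("features shift and scale the way clock geometry demands", {
  s <- mk_cosinor(50, 20, 10, days = 4, noise_sd = 5)
  f <- fit_cosinor(s)

  # whole-series shift by exactly 24 h: parameters unchanged
  s24 <- s
  s24$timestamp <- s24$timestamp + 86400
  f24 <- fit_cosinor(s24)
  expect_equal(f24$amplitude, f$amplitude, tolerance = 1e-9)
  expect_equal(f24$acrophase, f$acrophase, tolerance = 1e-9)

  # delta-hour shift moves the acrophase by delta (mod 24)
  s3 <- s
  s3$timestamp <- s3$timestamp + 3 * 3600
  f3 <- fit_cosinor(s3)
  expect_equal((f3$acrophase - f$acrophase) %% 24, 3, tolerance = 1e-6)

  # scale equivariance
  sc <- s; sc$enmo_mg <- sc$enmo_mg * 2.5
  fc <- fit_cosinor(sc)
  expect_equal(fc$mesor, 2.5 * f$mesor, tolerance = 1e-9)
  expect_equal(fc$amplitude, 2.5 * f$amplitude, tolerance = 1e-9)
  np <- nonparametric_metrics(s); npc <- nonparametric_metrics(sc)
  expect_equal(npc$interdaily_stability, np$interdaily_stability,
               tolerance = 1e-9)
  expect_equal(npc$intradaily_variability, np$intradaily_variability,
               tolerance = 1e-9)
  expect_equal(npc$relative_amplitude, np$relative_amplitude,
               tolerance = 1e-9)
  expect_equal(npc$m10, 2.5 * np$m10, tolerance = 1e-9)
  d <- dfa_exponents(s); dc <- dfa_exponents(sc)
  expect_equal(dc$dfa1, d$dfa1, tolerance = 1e-9)
})
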