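test_that("IS is 1 for an exactly 24-h-periodic series and bounded in general", {
  # arbitrary repeating daily pattern, 7 days
  set.seed(2)
  day <- runif(1440, 0, 100)
  s <- mk_series(rep(day, 7))
  np <- nonparametric_metrics(s)
  expect_equal(np$interdaily_stability, 1, tolerance = 1e-12)

  for (seed in 1:5) {
    set.seed(seed)
    s2 <- mk_series(pmax(rnorm(4 * 1440, 40, 30), 0))
    is_ <- nonparametric_metrics(s2)$interdaily_stability
    expect_gte(is_, 0); expect_lte(is_, 1)
  }
})

test_that("IV matches the sinusoid closed form and the white-noise limit", {
  s <- mk_cosinor(50, 20, 14, days = 7)
  np <- nonparametric_metrics(s)
  expect_lt(abs(np$intradaily_variability - 2 * (1 - cos(2 * pi / 24))), 2e-3)

  # iid hourly white noise, n = 168: IV concentrates near 2
  set.seed(9)
  s2 <- mk_series(rnorm(168, 50, 10), epoch_s = 3600)
  iv <- nonparametric_metrics(s2)$intradaily_variability
  expect_lt(abs(iv - 2), 0.15)

  flat <- nonparametric_metrics(mk_series(rep(5, 4 * 1440)))
  expect_true(is.na(flat$interdaily_stability))
  expect_true(is.na(flat$intradaily_variability))
})

test_that("M10/L5 and RA read off a constructed step profile", {
  # 10 h at 100 mg (08:00-18:00), rest at 10 mg, 3 identical days
  tod <- ((seq_len(3 * 1440) - 1) %% 1440) / 60
  y <- ifelse(tod >= 8 & tod < 18, 100, 10)
  np <- nonparametric_metrics(mk_series(y))
  expect_equal(np$m10, 100, tolerance = 1e-9)
  expect_equal(np$l5, 10, tolerance = 1e-9)
  expect_equal(np$relative_amplitude, 90 / 110, tolerance = 1e-9)
  expect_equal(np$m10_onset, 8, tolerance = 0.02)
})

test_that("DFA exponents match white-noise and random-walk theory", {
  set.seed(31)
  a_wn <- dfa_exponents(mk_series(rnorm(7 * 1440)))
  expect_lt(abs(a_wn$dfa1 - 0.5), 0.05)
  a_rw <- dfa_exponents(mk_series(cumsum(rnorm(7 * 1440))))
  expect_lt(abs(a_rw$dfa1 - 1.5), 0.1)
  expect_true(is.na(dfa_exponents(mk_series(rep(3, 7 * 1440)))$dfa1))
})

test_that("intensity features follow the cut-points and the 150-min boundary", {
  s <- mk_series(rep(150, 7 * 1440))
  f <- intensity_features(s)
  expect_equal(f$mvpa_hours, 24)
  expect_equal(f$sedentary_hours, 0)
  expect_equal(f$insufficient_mvpa, 0L)

  # exactly 150 weekly minutes is sufficient; 140 is not (boundary inclusive)
  base <- rep(50, 1440)
  mk_wk <- function(mins) {   # vector of minutes per day, length 7
    days <- lapply(mins, function(m) {
      day <- base; if (m > 0) day[700 + seq_len(m)] <- 200; day
    })
    mk_series(unlist(days))
  }
  f150 <- intensity_features(mk_wk(c(rep(21, 6), 24)))  # exactly 150/wk
  expect_equal(f150$weekly_mvpa_min, 150, tolerance = 1e-9)
  expect_equal(f150$insufficient_mvpa, 0L)
  f140 <- intensity_features(mk_wk(rep(20, 7)))
  expect_equal(f140$insufficient_mvpa, 1L)

  expect_error(intensity_features(dplyr::mutate(s, wear = FALSE)), "wear")
})

test_that("intensity gradient equals an independent log-log regression", {
  # construct epochs whose bin occupancy follows an exact power law
  mids <- seq(12.5, 4000, by = 25)
  counts <- round(2e5 * mids^-2)
  keep <- counts > 0
  y <- rep(mids[keep], counts[keep])
  y <- y[seq_len(min(length(y), 7 * 1440))]
  length(y) <- 7 * 1440
  y[is.na(y)] <- 12.5
  f <- intensity_features(mk_series(y))
  # oracle: tabulate minutes per bin, regress by hand
  tab <- table(factor(findInterval(y, seq(0, 4000, 25), rightmost.closed = TRUE)))
  xm <- mids[as.integer(names(tab))]
  o <- coef(lm(log(as.numeric(tab)) ~ log(xm)))
  expect_equal(f$intensity_gradient, unname(o[2]), tolerance = 1e-8)
})

test_that("sleep detector reads a constructed night correctly", {
  # zero activity 23:00-07:00, 120 mg otherwise, 4 days
  tod <- ((seq_len(4 * 1440) - 1) %% 1440) / 60
  y <- ifelse(tod >= 23 | tod < 7, 0, 120)
  sl <- sleep_metrics(mk_series(y))
  expect_equal(sl$sleep_onset, 23, tolerance = 0.1)
  expect_equal(sl$sleep_duration, 8, tolerance = 0.1)
  expect_equal(sl$sleep_efficiency, 1, tolerance = 0.01)
  expect_equal(sl$irregular_sleep, 0L)

  # three 10-min interruptions (each under the 20-min merge limit):
  # the window still spans the night and efficiency drops to 7.5/8
  y2 <- y
  for (st in c(0.5, 2.5, 4.5)) {          # hours after midnight
    idx <- which(tod >= st & tod < st + 1 / 6)
    y2[idx] <- 400
  }
  sl2 <- sleep_metrics(mk_series(y2))
  expect_equal(sl2$sleep_duration, 8, tolerance = 0.15)
  expect_equal(sl2$sleep_efficiency, 7.5 / 8, tolerance = 0.01)
})

test_that("nightly duration SD above 90 minutes flags irregular sleep", {
  # nights of 6, 8, 10, 6 hours -> SD 1.9 h > 1.5 h
  durs <- c(6, 8, 10, 6, 8)
  n_days <- length(durs) + 1
  tod <- ((seq_len(n_days * 1440) - 1) %% 1440) / 60
  day <- floor((seq_len(n_days * 1440) - 1) / 1440) + 1
  y <- rep(120, n_days * 1440)
  for (k in seq_along(durs)) {
    on <- which(day == k & tod >= 23)          # sleep starts 23:00
    after <- which(day == k + 1 & tod < durs[k] - 1)
    y[c(on, after)] <- 0
  }
  sl <- sleep_metrics(mk_series(y))
  expect_equal(sl$irregular_sleep, 1L)
  expect_gt(sl$sleep_duration_sd * 60, 90)
})

test_that("regularity screen excludes exactly the constructed extremes", {
  set.seed(5)
  f <- tibble::tibble(interdaily_stability = seq(0.01, 1, length.out = 100),
                      intradaily_variability = sample(seq(0.1, 2, length.out = 100)))
  mask <- regularity_screen(f)
  worst_is <- order(f$interdaily_stability)[1:5]
  worst_iv <- order(-f$intradaily_variability)[1:5]
  excluded <- which(!mask)
  expect_setequal(excluded, union(worst_is, worst_iv))

  # identical metrics: everyone retained
  same <- tibble::tibble(interdaily_stability = rep(0.5, 30),
                         intradaily_variability = rep(0.8, 30))
  expect_true(all(regularity_screen(same)))

  expect_warning(m <- regularity_screen(same[1:10, ]), "skipped")
  expect_true(all(m))
})

test_that("fragmented phenotype subjects fail the screen more often", {
  co <- shared_cohort()
  fe <- cohort_features(co, screen = FALSE)
  frag <- co$truth$fragmented
  skip_if(sum(frag) < 2, "no fragmented subjects drawn")
  mask <- regularity_screen(fe)
  expect_gt(mean(!mask[frag]), mean(!mask[!frag]))
})

test_that("fPCA recovers constructed eigenstructure", {
  # identical profiles: zero scores and zero explained variance
  p0 <- matrix(rep(sin(seq(0, 2 * pi, length.out = 100)), 12),
               nrow = 12, byrow = TRUE)
  f0 <- fpca_profiles(p0, n_components = 3)
  expect_lt(max(abs(f0$scores$fpc1)), 1e-8)
  expect_equal(sum(f0$explained_variance), 0, tolerance = 1e-12)

  # rank-1 data: PC1 recovers the shape up to sign, ~100% variance
  set.seed(7)
  shape <- sin(seq(0, 2 * pi, length.out = 200))
  load <- rnorm(30)
  m <- outer(load, shape) + matrix(rnorm(30 * 200, 0, 1e-6), 30)
  f1 <- fpca_profiles(m, n_components = 4)
  cc <- abs(cor(f1$components[, 1], shape))
  expect_gt(cc, 0.9999)
  expect_gt(f1$explained_variance[1], 0.999)

  # score orthogonality
  sc <- as.matrix(f1$scores)
  gram <- crossprod(sc)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)

  expect_error(fpca_profiles(m[1:3, ], n_components = 4), "subjects")
})
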