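#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generative model: population distributions of
#' the cosinor parameters (MESOR, amplitude, acrophase), day-to-day
#' variability, activity noise, the fragmented-rhythm phenotype, covariate
#' prevalences, the linear model for the systemic immune-inflammation index
#' (SII), and the Gompertz proportional-hazards mortality truth.
#'
#' Defaults are calibrated so that a large simulated cohort reproduces the
#' descriptive anchors of the population the package targets: median fitted
#' cosinor amplitude ~43 mg (IQR roughly 34-56), median acrophase ~13.9 h,
#' amplitude day-to-day CV ~60%, roughly half the cohort below 150 weekly
#' MVPA minutes, short-scale DFA exponent near 1, and a ~3-5% death rate
#' over 8 years of follow-up.
#'
#' @param n_subjects Number of subjects.
#' @param days Days of recording per subject.
#' @param epoch_s Epoch length in seconds; must divide 3600.
#' @param mesor_mult Multiplier linking subject MESOR to amplitude
#'   (`mesor = mesor_mult * amplitude`, mild heterogeneity added).
#' @param amplitude_dist Lognormal amplitude distribution,
#'   `list(meanlog, sdlog)` in log-mg.
#' @param acrophase_dist Normal acrophase distribution, `list(mean, sd)` in
#'   clock hours.
#' @param day_cv Day-to-day multiplicative coefficient of variation of the
#'   amplitude (lognormal multiplier, mean 1).
#' @param acro_day_sd Day-to-day SD of the acrophase, hours.
#' @param noise_sd Epoch-level activity noise SD in mg. The noise is 1/f
#'   (pink) Gaussian truncated so activity stays non-negative, which gives
#'   minute-level series the ~1.0 short-scale DFA exponent seen in adults.
#' @param frag_prob Probability of the fragmented-rhythm phenotype
#'   (amplitude shrunk by 70% plus hourly-block shuffling of 30% of epochs).
#' @param mvpa_dist Lognormal distribution of subject median daily MVPA-bout
#'   minutes, `list(meanlog, sdlog)`.
#' @param mvpa_day_sdlog Lognormal day-to-day sdlog of bout minutes.
#' @param sleep_damp Multiplier applied to activity inside the nightly
#'   rest window (8 h centered on the cosine trough, starting 8 h after
#'   the acrophase).
#' @param sii_coeffs Named coefficients (including `"(Intercept)"`) of the
#'   linear SII model over ground-truth columns; see [simulate_sii()].
#' @param sii_noise_sd Gaussian SII noise SD, index units.
#' @param gompertz_truth `list(a, b, beta)`: Gompertz shape (1/year), rate
#'   (1/year), and named log-hazard coefficients over ground-truth columns.
#' @param censor_years Administrative censoring horizon, years.
#' @param seed Integer seed; every draw descends deterministically from it.
#' @return A `rar_config` list.
#' @export
generator_config <- function(n_subjects = 500,
                             days = 7,
                             epoch_s = 60,
                             mesor_mult = 0.85,
                             amplitude_dist = list(meanlog = log(46), sdlog = 0.28),
                             acrophase_dist = list(mean = 13.9, sd = 1.1),
                             day_cv = 0.8,
                             acro_day_sd = 1.3,
                             noise_sd = 15,
                             frag_prob = 0.08,
                             mvpa_dist = list(meanlog = log(12), sdlog = 0.8),
                             mvpa_day_sdlog = 0.75,
                             sleep_damp = 0.10,
                             sii_coeffs = c("(Intercept)" = 600,
                                            amp_c = -3, irregular = 60,
                                            insuff_male = 100, age_c = 2,
                                            male = 30),
                             sii_noise_sd = 280,
                             gompertz_truth = list(
                               a = 0.09, b = 0.0022,
                               beta = c(age_c = 0.09, male = 0.55,
                                        amp_c = -0.015, irregular = 0.35,
                                        insufficient_mvpa = 0.25,
                                        sii_z = 0.25)),
                             censor_years = 8,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, days >= 1, 3600 %% epoch_s == 0,
            noise_sd >= 0, frag_prob >= 0, frag_prob <= 1)
  if (!is.numeric(amplitude_dist$meanlog) || exp(amplitude_dist$meanlog) <= 0)
    abort("amplitude distribution must have positive central value")
  cfg <- as.list(environment())
  structure(cfg, class = "rar_config")
}

#' Simulate one subject's minute-level activity series
#'
#' Generates a cosinor-structured ENMO trace: a daily cosine with
#' subject-level MESOR/amplitude/acrophase, day-to-day perturbations of
#' amplitude (lognormal multiplier) and acrophase (Gaussian jitter), an
#' optional damped nightly rest window, optional embedded MVPA bouts near
#' the acrophase, and truncated pink Gaussian noise. Values are in mg and
#' never negative.
#'
#' @param subject_params List with `mesor`, `amplitude`, `acrophase` (clock
#'   hours of peak activity) and optional `day_amp_sdlog`, `acro_day_sd`,
#'   `noise_sd`, `sleep_damp` (1 = no rest window), `mvpa_min` (median bout
#'   minutes/day), `mvpa_day_sdlog`, `frag` (fragmented phenotype flag).
#' @param days,epoch_s Recording length and epoch size (seconds).
#' @param seed Integer seed.
#' @param subject_id Identifier stamped on the output rows.
#' @param start Start timestamp (midnight) of the recording.
#' @return A tibble with `subject_id`, `timestamp`, `enmo_mg`, `wear`.
#' @examples
#' s <- simulate_activity_series(
#'   list(mesor = 50, amplitude = 20, acrophase = 14), days = 2, seed = 1)
#' @export
simulate_activity_series <- function(subject_params, days = 7, epoch_s = 60,
                                     seed = 1L, subject_id = "s1",
                                     start = as.POSIXct("2015-03-02 00:00:00",
                                                        tz = "UTC")) {
  p <- subject_params
  if (is.null(p$amplitude) || p$amplitude < 0)
    abort("amplitude must be given and non-negative")
  if (days < 1) abort("days must be >= 1")
  stopifnot(3600 %% epoch_s == 0)
  set.seed(seed)
  per_day <- 86400 %/% epoch_s
  n <- days * per_day
  dt_h <- epoch_s / 3600
  t_h <- (seq_len(n) - 1) * dt_h            # hours since start (midnight)
  tod <- t_h %% 24
  day_idx <- (seq_len(n) - 1) %/% per_day + 1

  day_amp_sdlog <- p$day_amp_sdlog %||% 0
  amp_mult <- if (day_amp_sdlog > 0)
    exp(rnorm(days, -day_amp_sdlog^2 / 2, day_amp_sdlog)) else rep(1, days)
  acro_sd <- p$acro_day_sd %||% 0
  acro_jit <- if (acro_sd > 0) rnorm(days, 0, acro_sd) else rep(0, days)

  amp_d <- p$amplitude * amp_mult[day_idx]
  acro_d <- p$acrophase + acro_jit[day_idx]
  y <- p$mesor + amp_d * cos(2 * pi * (t_h - acro_d) / 24)
  # the sustained circadian drive saturates; supra-MVPA minutes come from
  # the episodic bouts below, not from hours of elevated baseline
  cap <- p$baseline_cap %||% 75
  y <- pmin(y, cap)

  mvpa_min <- p$mvpa_min %||% 0
  if (mvpa_min > 0 && epoch_s == 60) {
    msd <- p$mvpa_day_sdlog %||% 0
    for (d in seq_len(days)) {
      # bouts track the day's jittered acrophase and scale with its
      # amplitude multiplier, so day-level fits see coherent variability
      ctr <- p$acrophase + acro_jit[d]
      tot <- mvpa_min * if (msd > 0) exp(rnorm(1, -msd^2 / 2, msd)) else 1
      left <- round(tot)
      while (left >= 4) {
        len <- max(4, min(left, round(rnorm(1, 10, 3))))
        st_h <- runif(1, ctr - 4, ctr + 4 - len / 60)
        i0 <- (d - 1) * per_day + floor((st_h %% 24) * 60) + 1
        idx <- i0:min(i0 + len - 1, d * per_day)
        y[idx] <- y[idx] + runif(1, 120, 300)
        left <- left - len
      }
    }
  }

  noise_sd <- p$noise_sd %||% 0
  if (noise_sd > 0) y <- y + noise_sd * pink_noise(n)

  # the nightly rest window damps everything, movement noise included
  sleep_damp <- p$sleep_damp %||% 1
  if (sleep_damp < 1) {
    rel <- (tod - (p$acrophase + 8)) %% 24   # hours into the rest window
    y[rel < 8] <- y[rel < 8] * sleep_damp
  }
  y <- pmax(y, 0)

  if (isTRUE(p$frag)) {
    # fragmented phenotype: shuffle 30% of hour blocks among themselves
    n_hours <- n %/% (3600 %/% epoch_s)
    pick <- sort(sample(n_hours, max(2, round(0.3 * n_hours))))
    perm <- sample(pick)
    per_h <- 3600 %/% epoch_s
    idx <- function(h) ((h - 1) * per_h + 1):(h * per_h)
    y2 <- y
    for (k in seq_along(pick)) y2[idx(pick[k])] <- y[idx(perm[k])]
    y <- y2
  }

  tibble::tibble(
    subject_id = subject_id,
    timestamp = start + (seq_len(n) - 1) * epoch_s,
    enmo_mg = y,
    wear = TRUE)
}

#' Simulate raw tri-axial acceleration consistent with an ENMO series
#'
#' Emits a tri-axial g-unit signal whose per-minute vector magnitude minus
#' 1 g (negatives zeroed) reproduces the input ENMO trace: within each
#' epoch the magnitude is held at `1 + enmo/1000` g while the orientation
#' rotates randomly, so [enmo_from_raw()] round-trips the input.
#'
#' @param series Epoch tibble with `timestamp` and `enmo_mg`.
#' @param sample_rate_hz Samples per second (>= 1).
#' @param seed Integer seed for the orientations.
#' @return A tibble with `t_s` (seconds from series start), `x_g`, `y_g`, `z_g`.
#' @export
simulate_raw_triaxial <- function(series, sample_rate_hz = 10, seed = 1L) {
  if (nrow(series) == 0) abort("empty series")
  stopifnot(sample_rate_hz >= 1)
  set.seed(seed)
  epoch_s <- as.numeric(difftime(series$timestamp[2], series$timestamp[1],
                                 units = "secs"))
  if (is.na(epoch_s)) epoch_s <- 60
  k <- round(epoch_s * sample_rate_hz)
  mag <- rep(1 + series$enmo_mg / 1000, each = k)
  ns <- length(mag)
  # random orientations on the unit sphere
  u <- rnorm(ns); v <- rnorm(ns); w <- rnorm(ns)
  nrm <- sqrt(u^2 + v^2 + w^2)
  tibble::tibble(
    t_s = (seq_len(ns) - 1) / sample_rate_hz,
    x_g = mag * u / nrm, y_g = mag * v / nrm, z_g = mag * w / nrm)
}

#' Simulate SII values and consistent blood counts
#'
#' The systemic immune-inflammation index is drawn as a linear function of
#' the supplied feature columns plus Gaussian noise, floored at a small
#' positive value. Platelet and lymphocyte counts are drawn around typical
#' adult values and the neutrophil count is then solved from the identity
#' SII = platelets x neutrophils / lymphocytes, which therefore holds
#' exactly for every row.
#'
#' @param features Data frame of predictor columns (one row per subject).
#' @param sii_coeffs Named numeric vector; names must be `"(Intercept)"`
#'   plus columns of `features`.
#' @param noise_sd Gaussian noise SD (index units).
#' @param seed Integer seed.
#' @param floor Minimum emitted SII.
#' @return Tibble with `sii`, `platelets` (10^9/L), `neutrophils`,
#'   `lymphocytes`.
#' @export
simulate_sii <- function(features, sii_coeffs, noise_sd = 280, seed = 1L,
                         floor = 10) {
  nm <- setdiff(names(sii_coeffs), "(Intercept)")
  miss <- setdiff(nm, names(features))
  if (length(miss))
    abort(sprintf("sii_coeffs name(s) not in features: %s",
                  paste(miss, collapse = ", ")))
  n <- nrow(features)
  lp <- rep(unname(sii_coeffs["(Intercept)"] %||% 0), n)
  for (v in nm) lp <- lp + sii_coeffs[[v]] * features[[v]]
  set.seed(derive_seed(seed, 1L))
  sii <- pmax(lp + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0, floor)
  set.seed(derive_seed(seed, 2L))
  plt <- pmax(rnorm(n, 250, 40), 100)
  set.seed(derive_seed(seed, 3L))
  lym <- pmax(rnorm(n, 2, 0.4), 0.5)
  tibble::tibble(sii = sii, platelets = plt,
                 neutrophils = sii * lym / plt, lymphocytes = lym)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate Gompertz survival times with administrative censoring
#'
#' Event times are drawn by inverting the Gompertz proportional-hazards
#' survival function S(t) = exp(-(b/a)(e^(at) - 1) e^eta); `a = 0` falls
#' back to the exponential limit. Times beyond `censor_years` are censored.
#'
#' @param linear_predictor Numeric vector eta (log-hazard scale).
#' @param gompertz_truth List with shape `a` (1/year) and rate `b` (1/year).
#' @param censor_years Administrative censoring horizon.
#' @param seed Integer seed.
#' @return Tibble with `time` (years, > 0) and `event` (0/1).
#' @export
simulate_survival <- function(linear_predictor, gompertz_truth,
                              censor_years = 8, seed = 1L) {
  a <- gompertz_truth$a; b <- gompertz_truth$b
  if (is.null(b) || b <= 0) abort("Gompertz rate b must be > 0")
  set.seed(seed)
  n <- length(linear_predictor)
  e <- rexp(n)                       # cumulative hazard at the event time
  z <- e * exp(-linear_predictor) / b
  t_event <- if (abs(a) < 1e-12) z else log1p(a * z) / a
  event <- as.integer(t_event <= censor_years)
  tibble::tibble(time = pmin(t_event, censor_years), event = event)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject rhythm parameters, covariates, activity traces, SII
#' with consistent blood counts, and Gompertz survival, all deterministically
#' from the config seed (per-subject streams are derived from
#' (seed, subject index), so cohorts reproduce under subsetting).
#'
#' @param config A [generator_config()].
#' @param include_epochs Keep per-subject epoch tibbles in the bundle
#'   (set `FALSE` to save memory and regenerate on demand).
#' @return A `rar_cohort` list with elements `epochs` (named list of epoch
#'   tibbles or `NULL`), `covariates`, `blood`, `survival`, `truth`,
#'   and `config`.
#' @export
simulate_cohort <- function(config = generator_config(), include_epochs = TRUE) {
  cfg <- config
  n <- cfg$n_subjects
  ids <- sprintf("S%05d", seq_len(n))

  # each quantity draws from its own seeded stream so that subject i's
  # parameters do not depend on the cohort size (subset reproducibility)
  draw <- local({
    k <- 0L
    function(expr) {
      k <<- k + 1L
      set.seed(derive_seed(cfg$seed, 1000L + k))
      expr
    }
  })
  amp <- draw(rlnorm(n, cfg$amplitude_dist$meanlog, cfg$amplitude_dist$sdlog))
  acro <- draw(rnorm(n, cfg$acrophase_dist$mean, cfg$acrophase_dist$sd))
  mesor <- amp * cfg$mesor_mult * draw(exp(rnorm(n, 0, 0.08)))
  frag <- draw(runif(n) < cfg$frag_prob)
  amp[frag] <- amp[frag] * 0.3
  mvpa_min <- draw(rlnorm(n, cfg$mvpa_dist$meanlog, cfg$mvpa_dist$sdlog))

  age <- draw(pmin(pmax(rnorm(n, 57, 8), 40), 70))
  male <- draw(rbinom(n, 1, 0.40))
  covariates <- tibble::tibble(
    subject_id = ids,
    age = age,
    sex = ifelse(male == 1, "male", "female"),
    ethnicity = ifelse(draw(runif(n)) < 0.978, "white", "non-white"),
    tdi = draw(pmin(pmax(rnorm(n, -2.2, 2.8), -6.5), 10)),
    bmi_class = draw(sample(c("normal", "overweight", "obese"), n, TRUE,
                            prob = c(0.413, 0.412, 0.175))),
    employment = ifelse(draw(runif(n)) < 0.61, "paid", "unpaid"),
    shift_work = draw(runif(n)) < 0.072,
    smoking = draw(sample(c("never", "previous", "current"), n, TRUE,
                          prob = c(0.583, 0.355, 0.062))),
    alcohol = draw(sample(c("none", "lt3_per_week", "ge3_per_week"), n, TRUE,
                          prob = c(0.053, 0.451, 0.496))),
    sleep_disturbance = draw(runif(n)) < 0.25,
    hypertension = draw(runif(n)) < 0.234,
    diabetes = draw(runif(n)) < 0.034,
    cvd = draw(runif(n)) < 0.003,
    cancer = draw(runif(n)) < 0.149,
    neurodegenerative = draw(runif(n)) < 0.002,
    respiratory = draw(runif(n)) < 0.013)

  truth <- tibble::tibble(
    subject_id = ids,
    mesor_true = mesor, amplitude_true = amp, acrophase_true = acro,
    mvpa_min_true = mvpa_min, fragmented = frag,
    insufficient_mvpa = as.integer(mvpa_min * 7 < 150),
    male = male, age = age,
    amp_c = amp - 40, age_c = age - 58,
    irregular = as.integer(frag),
    insuff_male = as.integer(mvpa_min * 7 < 150) * male)

  blood <- simulate_sii(truth, cfg$sii_coeffs, cfg$sii_noise_sd,
                        seed = derive_seed(cfg$seed, 1L))
  blood <- dplyr::bind_cols(tibble::tibble(subject_id = ids), blood)
  truth$sii <- blood$sii
  truth$sii_z <- as.numeric(scale(blood$sii))

  beta <- cfg$gompertz_truth$beta
  eta <- rep(0, n)
  for (v in names(beta)) eta <- eta + beta[[v]] * truth[[v]]
  truth$eta_true <- eta
  surv <- simulate_survival(eta, cfg$gompertz_truth, cfg$censor_years,
                            seed = derive_seed(cfg$seed, 2L))
  surv <- dplyr::bind_cols(tibble::tibble(subject_id = ids), surv)

  epochs <- NULL
  if (include_epochs) {
    epochs <- purrr::map(seq_len(n), function(i) {
      simulate_subject_series(cfg, truth[i, ], derive_seed(cfg$seed, 10L + i))
    })
    names(epochs) <- ids
  }

  structure(list(epochs = epochs, covariates = covariates, blood = blood,
                 survival = surv, truth = truth, config = cfg),
            class = "rar_cohort")
}

# Build one subject's series from a ground-truth row (shared by the bundle
# and by streaming feature extraction).
simulate_subject_series <- function(cfg, tr, seed) {
  day_sdlog <- sqrt(log(1 + cfg$day_cv^2))
  simulate_activity_series(
    list(mesor = tr$mesor_true, amplitude = tr$amplitude_true,
         acrophase = tr$acrophase_true,
         day_amp_sdlog = day_sdlog, acro_day_sd = cfg$acro_day_sd,
         noise_sd = cfg$noise_sd, sleep_damp = cfg$sleep_damp,
         mvpa_min = tr$mvpa_min_true, mvpa_day_sdlog = cfg$mvpa_day_sdlog,
         frag = isTRUE(as.logical(tr$fragmented))),
    days = cfg$days, epoch_s = cfg$epoch_s, seed = seed,
    subject_id = tr$subject_id)
}

#' @export
print.rar_cohort <- function(x, ...) {
  cat(sprintf("<rar_cohort> %d subjects, %d days, seed %d\n",
              x$config$n_subjects, x$config$days, x$config$seed))
  cat(sprintf("  deaths: %d (%.1f%%)\n", sum(x$survival$event),
              100 * mean(x$survival$event)))
  invisible(x)
}

#' Write a cohort bundle to plain-text CSV artifacts
#'
#' @param cohort A `rar_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(covariates = file.path(dir, "covariates.csv"),
             blood = file.path(dir, "blood_counts.csv"),
             survival = file.path(dir, "survival.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  readr::write_csv(cohort$covariates, paths["covariates"])
  readr::write_csv(cohort$blood, paths["blood"])
  readr::write_csv(cohort$survival, paths["survival"])
  readr::write_csv(cohort$truth, paths["truth"])
  if (!is.null(cohort$epochs)) {
    ep <- dplyr::bind_rows(cohort$epochs)
    ep$timestamp <- format(ep$timestamp, "%Y-%m-%dT%H:%M:%S")
    ep$wear <- as.integer(ep$wear)
    paths <- c(paths, epochs = file.path(dir, "epochs.csv"))
    readr::write_csv(ep, paths["epochs"])
  }
  cfg <- cohort$config
  flat <- vapply(cfg[!vapply(cfg, is.list, TRUE)],
                 function(v) paste(format(v), collapse = ","), "")
  writeLines(paste0(names(flat), " = ", flat), file.path(dir, "config.txt"))
  invisible(paths)
}

#' Read an epoch CSV back into an epoch series tibble
#'
#' Expects the interchange layout written by [write_cohort_csv()]:
#' `subject_id`, ISO-8601 `timestamp`, `enmo_mg`, `wear` (0/1).
#'
#' @param path CSV path.
#' @return Epoch tibble with POSIXct timestamps and logical `wear`.
#' @export
read_epoch_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  assert_cols(d, c("subject_id", "timestamp", "enmo_mg", "wear"), "epoch CSV")
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S"))
  d$wear <- as.logical(d$wear)
  tibble::as_tibble(d)
}
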