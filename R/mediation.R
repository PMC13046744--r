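#' Gaussian mediator model for natural-effects weighting
#'
#' Linear regression of the continuous mediator on the binary exposure and
#' covariates; the fitted conditional densities supply the density-ratio
#' weights of the natural-effects estimator.
#'
#' @param data Data frame.
#' @param mediator,exposure Column names (mediator continuous, exposure
#'   binary 0/1).
#' @param covariates Adjustment columns.
#' @return A `mediator_model`: the `lm` fit plus residual SD.
#' @export
fit_mediator_model <- function(data, mediator, exposure,
                               covariates = character()) {
  assert_cols(data, c(mediator, exposure, covariates), "data")
  f <- as.formula(paste(mediator, "~",
                        paste(c(exposure, covariates), collapse = " + ")))
  fit <- lm(f, data = data)
  sig <- suppressWarnings(summary(fit)$sigma)
  if (!is.finite(sig) || sig <= 1e-10)
    abort("mediator model has zero residual variance")
  structure(list(fit = fit, sigma = sig, mediator = mediator,
                 exposure = exposure, covariates = covariates),
            class = "mediator_model")
}

# Gaussian density of the observed mediator under a hypothetical exposure.
mediator_density <- function(mm, data, exposure_value) {
  nd <- data
  nd[[mm$exposure]] <- exposure_value
  mu <- predict(mm$fit, newdata = nd)
  stats::dnorm(data[[mm$mediator]], mean = mu, sd = mm$sigma)
}

#' Natural-effects decomposition of a survival exposure effect
#'
#' Weighting-based counterfactual mediation for a binary exposure, a
#' continuous mediator, and a right-censored survival outcome. The data
#' set is expanded with a hypothetical exposure level x* in \{0, 1\}; each
#' expanded row is weighted by the mediator density ratio
#' f(M | x*, C) / f(M | X, C) from the Gaussian mediator model, and a
#' proportional-hazards model (via [survival::coxph()]) is fitted on the
#' expanded weighted data with terms (x, x*, C). The natural direct effect
#' is exp(coef on x), the natural indirect effect exp(coef on x*), and the
#' total effect their product, so log TE = log NDE + log NIE holds by
#' construction.
#'
#' @param data Data frame with `time`, `event`, exposure, mediator,
#'   covariates.
#' @param exposure Binary exposure column (1 = adverse).
#' @param mediator Continuous mediator column (e.g. z-scored SII).
#' @param covariates Adjustment columns.
#' @param time,event Survival column names.
#' @param truncate_weights Optional quantile (e.g. 0.01) at which weights
#'   are winsorized; `NULL` leaves them untouched (a warning fires when
#'   max/min exceeds 1e3).
#' @param engine `"cox"` (semiparametric, default) or `"gompertz"`: the
#'   parametric proportional-hazards fallback fitted by weighted maximum
#'   likelihood, useful for tiny constructed examples where partial
#'   likelihood is degenerate.
#' @return A `rar_mediation` tibble: one row per effect (`nde`, `nie`,
#'   `te`) with `hr` and `log_hr`, plus `proportion_mediated` attached as
#'   an attribute and repeated in the `te` row.
#' @export
natural_effects_cox <- function(data, exposure, mediator,
                                covariates = character(),
                                time = "time", event = "event",
                                truncate_weights = NULL,
                                engine = c("cox", "gompertz")) {
  engine <- match.arg(engine)
  assert_cols(data, c(exposure, mediator, covariates, time, event), "data")
  x <- as.integer(data[[exposure]])
  if (!all(x %in% c(0L, 1L))) abort("exposure must be binary 0/1")
  if (min(tapply(data[[event]], x, sum)) < 1)
    abort("an exposure arm has no events")
  n <- length(x)
  # covariate design (factors expanded); shared by mediator and Cox models
  Cm <- if (length(covariates)) {
    cm <- stats::model.matrix(~., data = data[, covariates, drop = FALSE])
    cm[, -1, drop = FALSE]
  } else matrix(0, n, 0)

  # Gaussian mediator model M ~ x + C by least squares
  m <- as.numeric(data[[mediator]])
  Z <- cbind(1, x, Cm)
  mf <- stats::lm.fit(Z, m)
  sigma <- sqrt(sum(mf$residuals^2) / (n - ncol(Z)))
  if (!is.finite(sigma) || sigma <= 1e-10)
    abort("mediator model has zero residual variance")
  be <- mf$coefficients
  mu_base <- as.numeric(cbind(1, 0, Cm) %*% ifelse(is.na(be), 0, be))
  mu0 <- mu_base
  mu1 <- mu_base + be[2]
  d0 <- stats::dnorm(m, mu0, sigma); d1 <- stats::dnorm(m, mu1, sigma)
  dobs <- ifelse(x == 1L, d1, d0)
  w <- c(d0, d1) / rep(dobs, 2)
  if (is.null(truncate_weights)) {
    if (max(w) / max(min(w), 1e-300) > 1e3)
      warn("extreme natural-effects weights (max/min > 1e3); consider truncate_weights")
  } else {
    lo <- pct(w, truncate_weights); hi <- pct(w, 1 - truncate_weights)
    w <- pmin(pmax(w, lo), hi)
  }

  X <- cbind(.x = rep(x, 2), .xstar = rep(c(0L, 1L), each = n),
             rbind(Cm, Cm))
  if (engine == "cox") {
    yy <- survival::Surv(rep(as.numeric(data[[time]]), 2),
                         rep(as.integer(data[[event]]), 2))
    fit <- survival::coxph.fit(X, yy, strata = NULL, offset = NULL,
                               init = NULL,
                               control = survival::coxph.control(),
                               weights = w, method = "efron",
                               rownames = NULL)
    cf <- fit$coefficients
  } else {
    dg <- data.frame(time = rep(as.numeric(data[[time]]), 2),
                     event = rep(as.integer(data[[event]]), 2), X,
                     check.names = FALSE)
    fit <- fit_gompertz_ph(dg, colnames(X), weights = w)
    cf <- fit$coefficients
  }
  mm <- structure(list(beta = be, sigma = sigma, mediator = mediator,
                       exposure = exposure, covariates = covariates),
                  class = "mediator_density_model")
  log_nde <- unname(cf[".x"]); log_nie <- unname(cf[".xstar"])
  log_te <- log_nde + log_nie
  pm <- if (abs(log_te) > 0) log_nie / log_te else NA_real_
  out <- tibble::tibble(
    effect = c("nde", "nie", "te"),
    hr = exp(c(log_nde, log_nie, log_te)),
    log_hr = c(log_nde, log_nie, log_te),
    proportion_mediated = c(NA, NA, pm))
  attr(out, "cox_fit") <- fit
  attr(out, "mediator_model") <- mm
  class(out) <- c("rar_mediation", class(out))
  out
}

#' Proportion of a total effect mediated
#'
#' ln(NIE hazard ratio) / ln(TE hazard ratio).
#'
#' @param nie_hr,te_hr Hazard ratios.
#' @return Fraction (NA with a warning when TE = 1).
#' @export
proportion_mediated <- function(nie_hr, te_hr) {
  if (any(te_hr == 1)) {
    warn("total effect HR of 1: proportion mediated undefined")
    return(ifelse(te_hr == 1, NA_real_, log(nie_hr) / log(te_hr)))
  }
  log(nie_hr) / log(te_hr)
}

#' Percentile bootstrap confidence intervals for a cohort estimator
#'
#' Resamples subjects with replacement, re-runs the estimator, and returns
#' per-statistic percentile intervals. Replicates that fail (e.g.
#' non-convergence on a degenerate resample) are dropped and counted; more
#' than 10% failures is an error.
#'
#' @param estimator Function `data -> named numeric vector`.
#' @param data Data frame resampled by row (one row per subject).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; replicate r uses a seed derived from
#'   (seed, r), so intervals are reproducible.
#' @param level Confidence level.
#' @return Tibble: `statistic`, `estimate`, `ci_low`, `ci_high`,
#'   `n_failed`; the replicate matrix is attached as attribute `"replicates"`.
#' @export
bootstrap_ci <- function(estimator, data, n_boot = 1000, seed = 1L,
                         level = 0.95) {
  est <- estimator(data)
  reps <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  n <- nrow(data)
  for (r in seq_len(n_boot)) {
    set.seed(derive_seed(seed, r))
    idx <- sample.int(n, n, replace = TRUE)
    reps[r, ] <- tryCatch(estimator(data[idx, , drop = FALSE]),
                          error = function(e) rep(NA_real_, length(est)))
  }
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * n_boot)
    abort(sprintf("%d/%d bootstrap replicates failed", n_failed, n_boot))
  alpha <- (1 - level) / 2
  out <- tibble::tibble(
    statistic = names(est),
    estimate = unname(est),
    ci_low = apply(reps[ok, , drop = FALSE], 2, pct, p = alpha),
    ci_high = apply(reps[ok, , drop = FALSE], 2, pct, p = 1 - alpha),
    n_failed = n_failed)
  attr(out, "replicates") <- reps[ok, , drop = FALSE]
  out
}

#' Sex-stratified mediation of mortality through inflammation
#'
#' For each sex and each adverse exposure (rhythm irregularity = lowest
#' interdaily-stability quartile, insufficient MVPA = below 150 weekly
#' minutes, low amplitude = lowest amplitude quartile), runs the
#' natural-effects decomposition with bootstrap percentile intervals and
#' reports TE/NDE/NIE hazard ratios and the proportion mediated.
#'
#' @param cohort Tibble with survival columns, `sex`, the mediator, the
#'   feature columns, and the mediation covariates.
#' @param mediator Mediator column (z-scored SII recommended).
#' @param covariates Adjustment set (e.g. age, deprivation, BMI,
#'   employment, shift work).
#' @param exposures Named list mapping exposure labels to binary columns
#'   already present in `cohort`; `NULL` builds the three defaults from
#'   `interdaily_stability`, `weekly_mvpa_min`/`mvpa_hours`, and
#'   `cosinor_amplitude`.
#' @param n_boot Bootstrap replicates (0 skips intervals).
#' @param seed Integer seed.
#' @param min_events Strata with fewer events are flagged unstable.
#' @return Tibble: `sex`, `exposure`, `effect`, `hr`, `ci_low`, `ci_high`,
#'   `proportion_mediated`, `n`, `n_events`, `unstable`.
#' @export
sex_stratified_mediation <- function(cohort, mediator = "sii_z",
                                     covariates = c("age", "tdi"),
                                     exposures = NULL, n_boot = 200,
                                     seed = 1L, min_events = 5) {
  d <- dplyr::as_tibble(cohort)
  if (is.null(exposures)) {
    d$low_amplitude <- as.integer(
      quartile_groups(d$cosinor_amplitude)$quartile == "Q1")
    d$irregularity <- as.integer(
      quartile_groups(d$interdaily_stability)$quartile == "Q1")
    wk <- if ("weekly_mvpa_min" %in% names(d)) d$weekly_mvpa_min else
      d$mvpa_hours * 60 * 7
    d$insufficient_mvpa_flag <- as.integer(wk < 150)
    exposures <- list(irregularity = "irregularity",
                      insufficient_mvpa = "insufficient_mvpa_flag",
                      low_amplitude = "low_amplitude")
  }
  sexes <- unique(as.character(d$sex))
  rows <- list()
  for (sx in sexes) {
    ds <- d[d$sex == sx, , drop = FALSE]
    for (ex in names(exposures)) {
      col <- exposures[[ex]]
      ev_per_arm <- tapply(ds$event, ds[[col]], sum)
      unstable <- length(ev_per_arm) < 2 || min(ev_per_arm) < min_events
      if (unstable)
        warn(sprintf("%s / %s: < %d events in an arm; estimates unstable",
                     sx, ex, min_events))
      point <- tryCatch(natural_effects_cox(ds, col, mediator, covariates),
                        error = function(e) NULL)
      if (is.null(point)) {
        warn(sprintf("%s / %s: inestimable (%s)", sx, ex, "no events in an arm"))
        rows[[length(rows) + 1]] <- tibble::tibble(
          sex = sx, exposure = ex, effect = c("nde", "nie", "te"),
          hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          proportion_mediated = NA_real_, n = nrow(ds),
          n_events = sum(ds$event), n_boot = 0L, unstable = TRUE)
        next
      }
      if (n_boot > 0) {
        estfun <- function(dd) {
          m <- natural_effects_cox(dd, col, mediator, covariates)
          setNames(m$log_hr, m$effect)
        }
        ci <- tryCatch(bootstrap_ci(estfun, ds, n_boot = n_boot, seed = seed),
                       error = function(e) NULL)
        if (is.null(ci)) {
          warn(sprintf("%s / %s: bootstrap failed; intervals set to NA",
                       sx, ex))
          ci_low <- ci_high <- rep(NA_real_, 3)
          unstable <- TRUE
        } else {
          ci_low <- exp(ci$ci_low); ci_high <- exp(ci$ci_high)
        }
      } else {
        ci_low <- ci_high <- rep(NA_real_, 3)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        sex = sx, exposure = ex, effect = point$effect, hr = point$hr,
        ci_low = ci_low, ci_high = ci_high,
        proportion_mediated = point$proportion_mediated,
        n = nrow(ds), n_events = sum(ds$event), n_boot = n_boot,
        unstable = unstable)
    }
  }
  dplyr::bind_rows(rows)
}
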