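# Shared clock bookkeeping for an epoch series: hours since the first
# midnight, time of day, and midnight-to-midnight day index.
series_clock <- function(series) {
  assert_cols(series, c("timestamp", "enmo_mg"), "epoch series")
  ts <- series$timestamp
  midnight0 <- as.POSIXct(trunc(ts[1], "days"))
  t_h <- as.numeric(difftime(ts, midnight0, units = "hours"))
  epoch_s <- if (length(ts) > 1)
    as.numeric(difftime(ts[2], ts[1], units = "secs")) else 60
  list(t_h = t_h, tod = t_h %% 24, day = floor(t_h / 24) + 1L,
       epoch_s = epoch_s)
}

series_wear <- function(series) {
  if ("wear" %in% names(series)) as.logical(series$wear) else
    rep(TRUE, nrow(series))
}

#' Convert raw tri-axial acceleration to epoch-level ENMO
#'
#' Computes the Euclidean norm of (x, y, z) per sample, subtracts one
#' gravitational unit, zeroes negative values, and averages within epochs.
#' Output is in milli-g.
#'
#' @param raw Tibble with `t_s` (seconds), `x_g`, `y_g`, `z_g`.
#' @param epoch_s Epoch length in seconds.
#' @param start Timestamp assigned to `t_s = 0`.
#' @return Epoch tibble with `timestamp`, `enmo_mg`, `wear`.
#' @export
enmo_from_raw <- function(raw, epoch_s = 60,
                          start = as.POSIXct("2015-03-02 00:00:00", tz = "UTC")) {
  if (is.null(raw) || nrow(raw) == 0) abort("empty raw signal")
  assert_cols(raw, c("t_s", "x_g", "y_g", "z_g"), "raw signal")
  mag <- sqrt(raw$x_g^2 + raw$y_g^2 + raw$z_g^2)
  enmo <- pmax(mag - 1, 0) * 1000
  ep <- floor(raw$t_s / epoch_s)
  agg <- tapply(enmo, ep, mean)
  tibble::tibble(
    timestamp = start + as.numeric(names(agg)) * epoch_s,
    enmo_mg = as.numeric(agg),
    wear = TRUE)
}

#' Wear-time quality control
#'
#' A recording fails QC when total wear time is below `min_hours` or when
#' any of the 24 hour-of-day bins has no wear epochs at all across the
#' recording (so the diurnal cycle is not fully covered).
#'
#' @param series Epoch tibble with `timestamp`, `enmo_mg`, `wear`.
#' @param min_hours Minimum total wear, hours.
#' @return One-row tibble: `pass`, `wear_hours`, `hours_covered`, `reason`.
#' @export
qc_wear <- function(series, min_hours = 72) {
  ck <- series_clock(series)
  wear <- series_wear(series)
  wear_hours <- sum(wear) * ck$epoch_s / 3600
  covered <- unique(floor(ck$tod[wear]))
  n_cov <- length(intersect(0:23, covered))
  reason <- "pass"
  if (wear_hours < min_hours) {
    reason <- sprintf("insufficient wear (%.1f h < %g h)", wear_hours, min_hours)
  } else if (n_cov < 24) {
    reason <- sprintf("no wear data in %d hour-of-day bin(s)", 24 - n_cov)
  }
  tibble::tibble(pass = reason == "pass", wear_hours = wear_hours,
                 hours_covered = n_cov, reason = reason)
}

#' Fit a single-component cosinor model
#'
#' Fits Y(t) = M + A cos(2 pi (t - t_peak) / tau) by ordinary least squares:
#' the nonlinear cosine fit is linearized onto the basis
#' \{1, cos(wt), sin(wt)\}, after which amplitude and acrophase follow from
#' the two linear coefficients. The acrophase is the clock time of the
#' fitted maximum; the up-mesor, the upward MESOR crossing, sits a quarter
#' period earlier. The pseudo-F statistic compares the rhythm model to a
#' flat one: (model SS / 2) / (residual SS / (n - 3)).
#'
#' @param series Epoch tibble (`timestamp`, `enmo_mg`, optional `wear`).
#' @param period Fixed period in hours (default 24).
#' @param period_search If `TRUE`, the best-fitting period is found by a
#'   grid search over `period_bounds` followed by golden-section refinement
#'   of the residual sum of squares.
#' @param period_bounds Search bounds in hours.
#' @param min_hours Minimum wear needed to fit (two full days).
#' @return A `cosinor_fit` object; see [tidy.cosinor_fit()].
#' @examples
#' t <- seq(0, 48, by = 1 / 60)
#' s <- tibble::tibble(
#'   timestamp = as.POSIXct("2015-03-02", tz = "UTC") + t * 3600,
#'   enmo_mg = 50 + 20 * cos(2 * pi * (t - 14) / 24), wear = TRUE)
#' fit_cosinor(s)
#' @export
fit_cosinor <- function(series, period = 24, period_search = FALSE,
                        period_bounds = c(23, 25), min_hours = 48) {
  ck <- series_clock(series)
  wear <- series_wear(series) & is.finite(series$enmo_mg)
  t <- ck$t_h[wear]; y <- series$enmo_mg[wear]
  n <- length(y)
  if (n * ck$epoch_s / 3600 < min_hours)
    abort(sprintf("insufficient data for cosinor fit (< %g h of wear)", min_hours))

  rss_at <- function(tau) cosinor_ols(t, y, tau)$rss
  if (period_search) {
    grid <- seq(period_bounds[1], period_bounds[2], by = 0.05)
    r <- vapply(grid, rss_at, 0)
    i <- which.min(r)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    period <- stats::optimize(rss_at, c(lo, hi), tol = 1e-6)$minimum
  }
  f <- cosinor_ols(t, y, period)

  mss <- sum((f$fitted - mean(y))^2)
  pseudo_f <- if (f$rss > 0) (mss / 2) / (f$rss / (n - 3)) else Inf
  amp_defined <- f$amplitude > sqrt(.Machine$double.eps) * max(1, abs(f$mesor))
  if (!amp_defined) pseudo_f <- 0

  # hourly mean profile retained for plotting
  prof <- tapply(y, floor(t %% 24), mean)
  profile <- as.numeric(prof[as.character(0:23)])

  structure(list(
    mesor = f$mesor,
    amplitude = if (amp_defined) f$amplitude else 0,
    acrophase = if (amp_defined) f$acrophase else NA_real_,
    up_mesor = if (amp_defined) (f$acrophase - period / 4) %% 24 else NA_real_,
    period = period,
    pseudo_f = pseudo_f,
    rss = f$rss,
    n = n,
    acrophase_defined = amp_defined,
    profile = profile), class = "cosinor_fit")
}

# Linearized least squares at a fixed period.
cosinor_ols <- function(t, y, tau) {
  w <- 2 * pi / tau
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  amp <- sqrt(b[2]^2 + b[3]^2)
  acro <- (atan2(b[3], b[2]) / w) %% 24
  list(mesor = unname(b[1]), amplitude = unname(amp),
       acrophase = unname(acro), rss = sum(fit$residuals^2),
       fitted = fit$fitted.values)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> MESOR %.2f mg, amplitude %.2f mg, acrophase %s, period %.2f h, pseudo-F %.1f\n",
    x$mesor, x$amplitude,
    if (x$acrophase_defined) sprintf("%.2f h", x$acrophase) else "undefined",
    x$period, x$pseudo_f))
  invisible(x)
}

#' Day-to-day variability of cosinor parameters
#'
#' Fits a fixed 24-h cosinor to each midnight-to-midnight day separately
#' and reports the coefficient of variation of the day-level estimates, in
#' percent. The CV uses the population SD (divisor n) over the mean.
#' Circular quantities (acrophase, up-mesor) are unwrapped first: daily
#' values are shifted by multiples of 24 h to lie within 12 h of their
#' median, then the usual SD/mean is taken on the unwrapped hours. The
#' relative amplitude of each day (M10 - L5)/(M10 + L5) on that day's
#' profile is included.
#'
#' @param series Epoch tibble.
#' @param min_wear_h Days with less wear than this are dropped.
#' @param min_days Fewer valid days than this returns an all-NA row with a
#'   warning.
#' @return One-row tibble of CVs (percent) plus `sleepless` day count; the
#'   per-day fits are attached as attribute `"daily"`.
#' @export
daily_cosinor_cv <- function(series, min_wear_h = 20, min_days = 3) {
  ck <- series_clock(series)
  wear <- series_wear(series) & is.finite(series$enmo_mg)
  out_na <- tibble::tibble(
    amplitude_cv = NA_real_, mesor_cv = NA_real_, acrophase_cv = NA_real_,
    up_mesor_cv = NA_real_, pseudo_f_cv = NA_real_,
    relative_amplitude_cv = NA_real_, n_days = 0L)

  days <- sort(unique(ck$day[wear]))
  rows <- list()
  for (d in days) {
    sel <- wear & ck$day == d
    if (sum(sel) * ck$epoch_s / 3600 < min_wear_h) next
    t <- ck$tod[sel]; y <- series$enmo_mg[sel]
    f <- cosinor_ols(t, y, 24)
    prof <- y[order(t)]
    m10 <- max(roll_window_mean(prof, round(10 * 3600 / ck$epoch_s)))
    l5 <- min(roll_window_mean(prof, round(5 * 3600 / ck$epoch_s)))
    ra <- if (m10 + l5 > 0) (m10 - l5) / (m10 + l5) else NA_real_
    mss <- sum((f$fitted - mean(y))^2)
    pf <- if (f$rss > 0) (mss / 2) / (f$rss / (length(y) - 3)) else Inf
    rows[[length(rows) + 1]] <- tibble::tibble(
      day = d, mesor = f$mesor, amplitude = f$amplitude,
      acrophase = f$acrophase, up_mesor = (f$acrophase - 6) %% 24,
      pseudo_f = pf, relative_amplitude = ra)
  }
  if (length(rows) < min_days) {
    warn(sprintf("only %d valid day(s); day-level CVs set to NA", length(rows)))
    return(out_na)
  }
  daily <- dplyr::bind_rows(rows)
  out <- tibble::tibble(
    amplitude_cv = cv_percent(daily$amplitude),
    mesor_cv = cv_percent(daily$mesor),
    acrophase_cv = circular_cv(daily$acrophase),
    up_mesor_cv = circular_cv(daily$up_mesor),
    pseudo_f_cv = cv_percent(daily$pseudo_f),
    relative_amplitude_cv = cv_percent(daily$relative_amplitude),
    n_days = nrow(daily))
  attr(out, "daily") <- daily
  out
}

# CV (%) of clock-hour values after unwrapping around the median.
circular_cv <- function(h) {
  h <- h[is.finite(h)]
  if (length(h) < 2) return(NA_real_)
  m <- median(h)
  un <- h - 24 * round((h - m) / 24)
  if (mean(un) == 0) return(NA_real_)
  100 * sqrt(mean((un - mean(un))^2)) / mean(un)
}

# Circular rolling means over a daily profile (wraps around midnight).
roll_window_mean <- function(x, k) {
  n <- length(x)
  k <- min(k, n)
  cs <- cumsum(c(0, c(x, x[seq_len(k)])))
  (cs[(k + 1):(k + n)] - cs[seq_len(n)]) / k
}
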