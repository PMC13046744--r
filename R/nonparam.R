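#' Nonparametric circadian metrics: IS, IV, RA, M10, L5
#'
#' Interdaily stability (IS) and intradaily variability (IV) are computed
#' on hourly means of the wear epochs. IS is the fraction of the hourly
#' variance explained by the average 24-h profile,
#' IS = n * sum_h (xbar_h - xbar)^2 / (p * sum_i (x_i - xbar)^2) with
#' p = 24 hour-of-day bins (the balanced ANOVA form; with incomplete days
#' the hour-of-day groups are weighted by their counts, which keeps IS in
#' \[0, 1\]). IV is the normalized mean square of successive hourly
#' differences, IV = n * sum (x_i - x_(i-1))^2 / ((n-1) * sum (x_i - xbar)^2).
#' M10 and L5 are the most and least active 10-h and 5-h means of the
#' average 24-h profile (circular rolling windows at epoch resolution), and
#' the relative amplitude is RA = (M10 - L5) / (M10 + L5).
#'
#' @param series Epoch tibble (`timestamp`, `enmo_mg`, optional `wear`).
#' @param min_days Minimum full days required.
#' @return One-row tibble: `interdaily_stability`, `intradaily_variability`,
#'   `relative_amplitude`, `m10`, `l5`, `m10_onset`, `l5_onset`.
#' @export
nonparametric_metrics <- function(series, min_days = 3) {
  ck <- series_clock(series)
  wear <- series_wear(series) & is.finite(series$enmo_mg)
  t <- ck$t_h[wear]; y <- series$enmo_mg[wear]
  if (diff(range(t)) < (min_days * 24 - 1))
    abort(sprintf("need at least %d full days", min_days))

  hour_abs <- floor(t)
  agg <- grp_mean(y, hour_abs)
  x <- as.numeric(agg)
  hod <- as.integer(names(agg)) %% 24L
  n <- length(x)
  xbar <- mean(x)
  tot <- sum((x - xbar)^2)
  if (tot == 0) {
    is_ <- NA_real_; iv <- NA_real_
  } else {
    gm <- grp_mean(x, hod)
    gn <- as.integer(table(hod))
    between <- sum(gn * (gm - xbar)^2)
    is_ <- between / tot
    iv <- n * sum(diff(x)^2) / ((n - 1) * tot)
  }

  # average 24-h profile at epoch resolution
  per_day <- round(86400 / ck$epoch_s)
  slot <- floor(ck$tod[wear] / 24 * per_day) + 1L
  prof <- as.numeric(grp_mean(y, slot))
  k10 <- round(10 * 3600 / ck$epoch_s); k5 <- round(5 * 3600 / ck$epoch_s)
  w10 <- roll_window_mean(prof, min(k10, length(prof)))
  w5 <- roll_window_mean(prof, min(k5, length(prof)))
  m10 <- max(w10); l5 <- min(w5)
  slot_h <- (sort(unique(slot)) - 1L) / per_day * 24
  ra <- if (m10 + l5 > 0) (m10 - l5) / (m10 + l5) else NA_real_

  tibble::tibble(
    interdaily_stability = is_, intradaily_variability = iv,
    relative_amplitude = ra, m10 = m10, l5 = l5,
    m10_onset = slot_h[which.max(w10)], l5_onset = slot_h[which.min(w5)])
}

#' Detrended fluctuation analysis scaling exponents
#'
#' The mean-centered series is integrated into a profile; for each window
#' size the profile is split into non-overlapping windows, a linear trend is
#' removed from each, and the fluctuation F(n) is the root-mean-square
#' residual. The scaling exponents are the slopes of log F(n) vs log n over
#' short (< `split_h` hours) and long (> `split_h`) window ranges. Alpha of
#' 0.5 indicates white noise, 1.0 pink (1/f) structure, 1.5 a random walk.
#'
#' @param series Epoch tibble of minute-level data.
#' @param short_min Smallest window, minutes.
#' @param split_h Boundary between short and long ranges, hours.
#' @param long_max_h Largest window, hours (capped at a quarter of the data).
#' @param n_scales Windows per decade-ish; scales are log-spaced.
#' @return One-row tibble with `dfa1` (short) and `dfa2` (long), plus the
#'   per-scale fluctuations as attribute `"fluctuation"`.
#' @export
dfa_exponents <- function(series, short_min = 4, split_h = 2, long_max_h = 27,
                          n_scales = 12) {
  ck <- series_clock(series)
  wear <- series_wear(series) & is.finite(series$enmo_mg)
  y <- series$enmo_mg[wear]
  n <- length(y)
  if (n < 3 * 1440 * 60 / ck$epoch_s) abort("need at least 3 days of epochs")
  if (sd(y) == 0) {
    return(tibble::tibble(dfa1 = NA_real_, dfa2 = NA_real_))
  }
  per_min <- 60 / ck$epoch_s
  split_n <- split_h * 60 * per_min
  long_max <- min(long_max_h * 60 * per_min, floor(n / 4))
  scales_s <- unique(round(exp(seq(log(short_min * per_min), log(split_n),
                                   length.out = n_scales))))
  scales_l <- unique(round(exp(seq(log(split_n), log(long_max),
                                   length.out = n_scales))))
  prof <- cumsum(y - mean(y))
  fl <- function(s) {
    k <- n %/% s
    m <- matrix(prof[seq_len(k * s)], nrow = s)
    tt <- seq_len(s)
    stt <- sum((tt - mean(tt))^2)
    cm <- colMeans(m)
    sty <- as.numeric(crossprod(tt - mean(tt), m))
    syy <- colSums(m^2) - s * cm^2
    rss <- pmax(syy - sty^2 / stt, 0)
    sqrt(sum(rss) / (k * s))
  }
  f1 <- vapply(scales_s, fl, 0)
  f2 <- vapply(scales_l, fl, 0)
  slope <- function(s, f) {
    ok <- f > 0
    if (sum(ok) < 3) return(NA_real_)
    unname(coef(lm(log(f[ok]) ~ log(s[ok])))[2])
  }
  out <- tibble::tibble(dfa1 = slope(scales_s, f1), dfa2 = slope(scales_l, f2))
  attr(out, "fluctuation") <- tibble::tibble(
    scale = c(scales_s, scales_l),
    range = rep(c("short", "long"), c(length(scales_s), length(scales_l))),
    f = c(f1, f2))
  out
}

#' Physical-activity intensity features
#'
#' MVPA and sedentary hours per day (mean over valid days) by the 100 mg
#' and 40 mg cut-points, their day-to-day CVs, the insufficient-MVPA flag
#' (weekly MVPA minutes below 150; 150 itself counts as sufficient), and
#' the intensity gradient: the slope of ln(minutes in bin) on ln(bin
#' midpoint) over 25-mg intensity bins spanning 0-4000 mg, empty bins
#' dropped.
#'
#' @param series Epoch tibble of minute-level data.
#' @param mvpa_cut,sed_cut Cut-points in mg.
#' @param min_wear_h Days with less wear are dropped from per-day stats.
#' @return One-row tibble: `mvpa_hours`, `mvpa_cv`, `weekly_mvpa_min`,
#'   `insufficient_mvpa`, `sedentary_hours`, `sedentary_cv`,
#'   `intensity_gradient`, `ig_intercept`.
#' @export
intensity_features <- function(series, mvpa_cut = 100, sed_cut = 40,
                               min_wear_h = 20) {
  ck <- series_clock(series)
  wear <- series_wear(series) & is.finite(series$enmo_mg)
  if (!any(wear)) abort("no wear epochs")
  ep_h <- ck$epoch_s / 3600
  d <- ck$day[wear]; y <- series$enmo_mg[wear]
  wear_h <- grp_sum(rep(ep_h, length(d)), d)
  valid <- names(wear_h)[wear_h >= min_wear_h]
  keep <- d %in% as.numeric(valid)
  d <- d[keep]; y <- y[keep]
  if (!length(y)) abort("no valid days after wear screening")
  mvpa_d <- grp_sum(y > mvpa_cut, d) * ep_h
  sed_d <- grp_sum(y < sed_cut, d) * ep_h
  weekly <- mean(mvpa_d) * 60 * 7

  mids <- seq(12.5, 4000, by = 25)
  bin <- pmin(findInterval(y, seq(0, 4000, by = 25),
                           rightmost.closed = TRUE), length(mids))
  minutes <- grp_sum(rep(ck$epoch_s / 60, length(bin)), bin)
  tm <- as.numeric(minutes); bm <- mids[as.numeric(names(minutes))]
  ok <- tm > 0
  ig <- coef(lm(log(tm[ok]) ~ log(bm[ok])))

  tibble::tibble(
    mvpa_hours = mean(mvpa_d), mvpa_cv = cv_percent(mvpa_d),
    weekly_mvpa_min = weekly,
    insufficient_mvpa = as.integer(weekly < 150),
    sedentary_hours = mean(sed_d), sedentary_cv = cv_percent(sed_d),
    intensity_gradient = unname(ig[2]), ig_intercept = unname(ig[1]))
}

#' Simplified sleep metrics from the activity trace
#'
#' For each noon-to-noon window the main sleep period is the longest block
#' of epochs whose 5-minute rolling ENMO stays below a rest threshold,
#' where sub-threshold runs separated by interruptions of at most
#' `max_interrupt_min` minutes are merged. Onset is reported as hours since
#' the midnight that starts the window's calendar day, so onsets after
#' midnight exceed 24. Efficiency is the fraction of raw epochs inside the
#' main sleep window that lie below the threshold. Nights are averaged;
#' the irregular-sleep flag fires when the SD of nightly duration exceeds
#' 90 minutes.
#'
#' @param series Epoch tibble of minute-level data.
#' @param rest_threshold Rest threshold, mg.
#' @param smooth_min Rolling-mean window, minutes.
#' @param max_interrupt_min Longest interruption merged into a sleep block.
#' @param min_windows Minimum qualifying nights; fewer (or qualifying
#'   windows on no more than half of nights) returns NA values.
#' @return One-row tibble: `sleep_onset` (clock-h, may exceed 24),
#'   `sleep_duration` (h), `sleep_efficiency`, `sleep_duration_sd` (h),
#'   `irregular_sleep`; per-night rows attached as attribute `"nights"`.
#' @export
sleep_metrics <- function(series, rest_threshold = 10, smooth_min = 5,
                          max_interrupt_min = 20, min_windows = 3) {
  ck <- series_clock(series)
  y <- series$enmo_mg
  ep_min <- ck$epoch_s / 60
  sm <- roll_mean(y, max(1, round(smooth_min / ep_min)))
  below <- sm < rest_threshold
  raw_below <- y < rest_threshold

  t_h <- ck$t_h
  n_win <- floor((max(t_h) - 12) / 24)
  if (n_win < min_windows) abort("need at least 3 noon-to-noon windows")
  nights <- list()
  for (w in seq_len(n_win)) {
    lo <- 12 + 24 * (w - 1); hi <- lo + 24
    sel <- which(t_h >= lo & t_h < hi)
    b <- below[sel]
    blk <- main_sleep_block(b, max_interrupt = round(max_interrupt_min / ep_min))
    if (is.null(blk)) next
    idx <- sel[blk[1]:blk[2]]
    onset <- t_h[idx[1]] - 24 * (w - 1)
    dur <- (length(idx) * ep_min) / 60
    eff <- mean(raw_below[idx])
    nights[[length(nights) + 1]] <- tibble::tibble(
      night = w, onset = onset, duration = dur, efficiency = eff)
  }
  if (length(nights) < min_windows || length(nights) <= n_win / 2) {
    return(tibble::tibble(sleep_onset = NA_real_, sleep_duration = NA_real_,
                          sleep_efficiency = NA_real_,
                          sleep_duration_sd = NA_real_,
                          irregular_sleep = NA_integer_))
  }
  nt <- dplyr::bind_rows(nights)
  out <- tibble::tibble(
    sleep_onset = mean(nt$onset),
    sleep_duration = mean(nt$duration),
    sleep_efficiency = mean(nt$efficiency),
    sleep_duration_sd = sd(nt$duration),
    irregular_sleep = as.integer(sd(nt$duration) * 60 > 90))
  attr(out, "nights") <- nt
  out
}

# Longest merged run of TRUE allowing interruptions of <= max_interrupt
# epochs; returns c(start, end) indices or NULL.
main_sleep_block <- function(b, max_interrupt, min_len = 60) {
  r <- rle(b)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(NULL)
  # merge TRUE runs separated by short FALSE gaps
  blocks <- list(c(starts[runs[1]], ends[runs[1]]))
  for (k in runs[-1]) {
    last <- blocks[[length(blocks)]]
    gap <- starts[k] - last[2] - 1
    if (gap <= max_interrupt) {
      blocks[[length(blocks)]] <- c(last[1], ends[k])
    } else {
      blocks[[length(blocks) + 1]] <- c(starts[k], ends[k])
    }
  }
  span <- vapply(blocks, function(bk) bk[2] - bk[1] + 1, 0)
  best <- blocks[[which.max(span)]]
  if (best[2] - best[1] + 1 < min_len) return(NULL)
  best
}

#' Regularity screen on cohort IS/IV
#'
#' Subjects are retained when interdaily stability is at or above the 5th
#' percentile and intradaily variability at or below the 95th percentile of
#' the sample distribution (linear-interpolation percentiles). With fewer
#' than 20 subjects the screen is skipped with a warning.
#'
#' @param features Data frame with `interdaily_stability` and
#'   `intradaily_variability` columns.
#' @return Logical inclusion mask with attribute `"thresholds"`.
#' @export
regularity_screen <- function(features) {
  assert_cols(features, c("interdaily_stability", "intradaily_variability"),
              "feature table")
  is_ <- features$interdaily_stability
  iv <- features$intradaily_variability
  if (nrow(features) < 20) {
    warn("fewer than 20 subjects; regularity screen skipped")
    return(rep(TRUE, nrow(features)))
  }
  lo <- pct(is_, 0.05); hi <- pct(iv, 0.95)
  mask <- !is.na(is_) & !is.na(iv) & is_ >= lo & iv <= hi
  attr(mask, "thresholds") <- c(is_p5 = lo, iv_p95 = hi)
  mask
}
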